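# Shared data model: a trajectory is an ordered set of frames of labeled
# beads. Coordinates are stored in nm; times in ns.

#' Construct a coarse-grained trajectory
#'
#' The container shared by all analysis stages: a bead topology (labels,
#' identical across frames) plus a `frames x beads x 3` coordinate array in
#' nanometres and a strictly increasing time vector in nanoseconds.
#'
#' @param topology data frame with one row per bead and columns `index`
#'   (0-based integer, unique), `name` (bead label, e.g. `"PO4"`, `"BB"`),
#'   `entity_kind` (`"protein"` or `"lipid"`), `species` (e.g. `"DMPC"`,
#'   `"DHPC"`, `"RHD"`), `role` (`"head"`, `"tail"`, `"backbone"`,
#'   `"sidechain"` or `"other"`) and `leaflet` (`"cytoplasmic"`,
#'   `"luminal"`, `"rim"` or `"unassigned"`).
#' @param coords numeric array of dimension `c(n_frames, n_beads, 3)`, nm.
#'   A single frame may be given as an `n_beads x 3` matrix.
#' @param times numeric vector of frame times (ns), strictly increasing.
#'   Defaults to `(0:(n_frames-1)) * timestep`.
#' @param timestep optional nominal frame spacing (ns); when set, successive
#'   time differences must equal it to within 1e-9 ns.
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, times = NULL, timestep = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  topology <- validate_topology(topology, n_beads = dim(coords)[2])
  n_frames <- dim(coords)[1]
  if (is.null(times)) {
    dt <- if (is.null(timestep)) 0.02 else timestep
    times <- (seq_len(n_frames) - 1) * dt
  }
  if (length(times) != n_frames) {
    stop("length(times) must equal the number of frames", call. = FALSE)
  }
  if (n_frames > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (any(times < 0)) stop("frame times must be non-negative", call. = FALSE)
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  if (!is.null(timestep) && n_frames > 1 &&
      any(abs(diff(times) - timestep) > 1e-9)) {
    stop("successive time differences do not match `timestep` within 1e-9 ns",
         call. = FALSE)
  }
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         timestep = timestep),
    class = "trajectory"
  )
}

bead_roles    <- c("head", "tail", "backbone", "sidechain", "other")
leaflet_labels <- c("cytoplasmic", "luminal", "rim", "unassigned")

validate_topology <- function(topology, n_beads = NULL) {
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  needed <- c("index", "name", "entity_kind", "species", "role", "leaflet")
  missing <- setdiff(needed, names(topology))
  if (length(missing)) {
    stop("topology lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(n_beads) && nrow(topology) != n_beads) {
    stop("topology has ", nrow(topology), " beads but coordinates have ",
         n_beads, call. = FALSE)
  }
  if (anyDuplicated(topology$index)) {
    stop("bead indices must be unique within a topology", call. = FALSE)
  }
  if (!all(topology$entity_kind %in% c("protein", "lipid"))) {
    stop("entity_kind must be 'protein' or 'lipid'", call. = FALSE)
  }
  if (!all(topology$role %in% bead_roles)) {
    stop("role must be one of: ", paste(bead_roles, collapse = ", "),
         call. = FALSE)
  }
  if (!all(topology$leaflet %in% leaflet_labels)) {
    stop("leaflet must be one of: ", paste(leaflet_labels, collapse = ", "),
         call. = FALSE)
  }
  topology
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d beads, t = %.4g..%.4g ns\n",
              n_frames(x), n_beads(x), x$times[1],
              x$times[length(x$times)]))
  kinds <- table(x$topology$entity_kind)
  cat("  beads: ", paste(sprintf("%s=%d", names(kinds), kinds),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of frames / beads in a trajectory
#' @param traj a [trajectory()] object.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_beads <- function(traj) dim(traj$coords)[2]

#' Extract one frame's coordinates
#' @param traj a [trajectory()] object.
#' @param i frame number (1-based).
#' @return `n_beads x 3` numeric matrix (nm).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Subset the frames of a trajectory
#' @param traj a [trajectory()] object.
#' @param idx frame indices (1-based, increasing).
#' @return trajectory with the selected frames.
#' @export
subset_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1), all(idx <= n_frames(traj)))
  trajectory(traj$topology,
             traj$coords[idx, , , drop = FALSE],
             times = traj$times[idx])
}

#' Select beads of a trajectory
#'
#' Returns the sub-trajectory of beads for which `selector` is true, in
#' original index order, with frame times preserved. Used e.g. to restrict a
#' curvature fit to long-chain lipid head beads or an RMSF calculation to
#' protein backbone beads.
#'
#' @param traj a [trajectory()] object.
#' @param selector one of: a logical vector over beads; an integer vector of
#'   1-based bead positions; a function taking the topology data frame and
#'   returning a logical vector; or a character string with an expression
#'   evaluated in the topology (e.g. `'role == "head" & species == "DMPC"'`).
#' @return trajectory restricted to the matching beads.
#' @export
select_beads <- function(traj, selector) {
  keep <- resolve_selector(traj$topology, selector)
  if (!any(keep)) stop("bead selection is empty", call. = FALSE)
  trajectory(traj$topology[keep, , drop = FALSE],
             traj$coords[, keep, , drop = FALSE],
             times = traj$times, timestep = traj$timestep)
}

resolve_selector <- function(topology, selector) {
  if (is.null(selector)) return(rep(TRUE, nrow(topology)))
  if (is.function(selector)) {
    keep <- selector(topology)
  } else if (is.character(selector) && length(selector) == 1L) {
    keep <- eval(parse(text = selector)[[1]], envir = topology,
                 enclos = parent.frame(2))
  } else if (is.logical(selector)) {
    keep <- selector
  } else if (is.numeric(selector)) {
    keep <- seq_len(nrow(topology)) %in% as.integer(selector)
  } else {
    stop("unsupported selector type", call. = FALSE)
  }
  keep <- as.logical(keep)
  if (length(keep) != nrow(topology) || anyNA(keep)) {
    stop("selector must resolve to one TRUE/FALSE per bead", call. = FALSE)
  }
  keep
}

# ---------------------------------------------------------------------------
# Bead label mapping

#' Default lipid-name registry
#'
#' Residue names listed here are mapped to `entity_kind = "lipid"` on input;
#' everything else is treated as protein. The `chain` column distinguishes
#' bilayer-forming long-chain lipids from the short-chain (rim-stabilizing)
#' species of a bicelle. Shipped as a plain TSV under `extdata/` so users can
#' pass an extended table.
#'
#' @return data frame with columns `species` and `chain`
#'   (`"long"`/`"short"`).
#' @export
default_lipid_registry <- function() {
  path <- system.file("extdata", "lipid_registry.tsv", package = "memshape")
  if (nzchar(path)) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    data.frame(species = c("DMPC", "DHPC", "POPC"),
               chain = c("long", "short", "long"),
               stringsAsFactors = FALSE)
  }
}

# Documented mapping from atom/residue names to bead labels. Head-group bead
# names follow MARTINI phospholipid conventions; "BB"/"SC*" follow MARTINI
# protein conventions.
role_from_name <- function(name) {
  up <- toupper(trimws(name))
  role <- rep("other", length(up))
  role[up %in% c("NC3", "PO4", "HD", "NH3", "CNO", "GL0", "P")] <- "head"
  role[grepl("^[CD][0-9]", up)] <- "tail"
  role[up == "BB"] <- "backbone"
  role[grepl("^SC", up)] <- "sidechain"
  role
}

# Leaflet labels round-trip through the PDB chain / GRO residue-name suffix.
leaflet_from_code <- function(code) {
  up <- toupper(trimws(code))
  out <- rep("unassigned", length(up))
  out[up == "C"] <- "cytoplasmic"
  out[up == "L"] <- "luminal"
  out[up == "R"] <- "rim"
  out
}

leaflet_to_code <- function(leaflet) {
  c(cytoplasmic = "C", luminal = "L", rim = "R", unassigned = "X")[leaflet]
}

build_topology <- function(names, species, leaflet_code,
                           lipid_registry = default_lipid_registry()) {
  species <- toupper(trimws(species))
  data.frame(
    index = seq_along(names) - 1L,
    name = trimws(names),
    entity_kind = ifelse(species %in% lipid_registry$species,
                         "lipid", "protein"),
    species = species,
    role = role_from_name(names),
    leaflet = leaflet_from_code(leaflet_code),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Readers

#' Read a labeled coordinate trajectory
#'
#' Supported dialects: multi-model PDB (`MODEL`/`ENDMDL` blocks, coordinates
#' in Angstrom, divided by 10 on read), concatenated GRO frames (nm; frame
#' time taken from a `t=` token in the title line when present), and plain
#' XYZ (nm). Frame times absent from the file default to `index * timestep`.
#' Bead labels are populated from atom and residue names via a documented
#' mapping: residues listed in the lipid-name registry become lipids (head
#' beads `NC3`/`PO4`/..., tail beads `C1A`-like), everything else protein
#' (`BB` backbone, `SC*` sidechain). Leaflet labels are recovered from the
#' PDB chain identifier (`C`/`L`/`R`) where present, else `"unassigned"`.
#'
#' Inputs are assumed to be whole (not wrapped across periodic boundaries);
#' making molecules whole is the caller's responsibility.
#'
#' @param path input file.
#' @param format `"pdb"`, `"gro"` or `"xyz"`. Defaults from the file
#'   extension.
#' @param timestep frame spacing (ns) used when the file carries no times.
#'   The default 0.02 ns corresponds to the conventional reporting of a
#'   20-fs coarse-grained integration step; the mapping of coarse-grained to
#'   physical time is contested, hence configurable.
#' @param lipid_registry see [default_lipid_registry()].
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path,
                            format = c("auto", "pdb", "gro", "xyz"),
                            timestep = 0.02,
                            lipid_registry = default_lipid_registry()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro", xyz = "xyz",
                     stop("cannot infer trajectory format from '", ext,
                          "'; pass `format`", call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         pdb = read_trajectory_pdb(path, timestep, lipid_registry),
         gro = read_trajectory_gro(path, timestep, lipid_registry),
         xyz = read_trajectory_xyz(path, timestep, lipid_registry))
}

read_trajectory_pdb <- function(path, timestep, lipid_registry) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nb <- ncol(xyz) / 3L
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, nb, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * nb, by = 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, 3 * nb, by = 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, 3 * nb, by = 3), drop = FALSE]
  coords <- coords / 10  # Angstrom -> nm
  topo <- build_topology(pdb$atom$elety, pdb$atom$resid, pdb$atom$chain,
                         lipid_registry)
  trajectory(topo, coords, times = (seq_len(nf) - 1) * timestep)
}

read_trajectory_gro <- function(path, timestep, lipid_registry) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  nb_ref <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) {
      stop("GRO parse error at line ", i, ": truncated frame header",
           call. = FALSE)
    }
    nb <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nb) || nb < 1) {
      stop("GRO parse error at line ", i + 1L, ": bad atom count",
           call. = FALSE)
    }
    if (i + 1L + nb + 1L > length(lines)) {
      stop("GRO parse error: frame starting at line ", i,
           " is truncated", call. = FALSE)
    }
    body <- lines[(i + 2L):(i + 1L + nb)]
    resname <- trimws(substr(body, 6, 10))
    atname  <- trimws(substr(body, 11, 15))
    x <- suppressWarnings(as.numeric(substr(body, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(body, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(body, 37, 44)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad)) {
      stop("GRO parse error at line ", i + 1L + bad[1],
           ": malformed coordinate record", call. = FALSE)
    }
    if (is.null(nb_ref)) {
      nb_ref <- nb
      topo_src <- list(atname = atname, resname = resname, body = body)
    } else if (nb != nb_ref) {
      stop("GRO structure error: frame starting at line ", i, " has ", nb,
           " beads, expected ", nb_ref, call. = FALSE)
    }
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) {
      as.numeric(sub("t=\\s*", "", tm))
    } else NA_real_)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    i <- i + 1L + nb + 2L  # title + count + atoms + box line
  }
  if (!length(frames)) stop("GRO parse error: no frames found", call. = FALSE)
  if (all(is.na(times))) {
    times <- (seq_along(frames) - 1) * timestep
  } else if (anyNA(times)) {
    stop("GRO structure error: `t=` present in some but not all frame titles",
         call. = FALSE)
  } else if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("GRO structure error: frame times are not strictly increasing",
         call. = FALSE)
  }
  coords <- array(NA_real_, dim = c(length(frames), nb_ref, 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  # leaflet code optionally carried as a residue-name suffix "_C"/"_L"/"_R"
  rn <- topo_src$resname
  leaf <- ifelse(grepl("_[CLR]$", rn), sub("^.*_", "", rn), "X")
  topo <- build_topology(topo_src$atname, sub("_[CLR]$", "", rn), leaf,
                         lipid_registry)
  trajectory(topo, coords, times = times)
}

read_trajectory_xyz <- function(path, timestep, lipid_registry) {
  lines <- readLines(path)
  frames <- list()
  names_ref <- NULL
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    nb <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nb) || nb < 1) {
      stop("XYZ parse error at line ", i, ": bad atom count", call. = FALSE)
    }
    if (i + 1L + nb > length(lines)) {
      stop("XYZ parse error: frame starting at line ", i, " is truncated",
           call. = FALSE)
    }
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nb)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad)) {
      stop("XYZ parse error at line ", i + 1L + bad[1],
           ": expected 'name x y z'", call. = FALSE)
    }
    nm <- vapply(toks, `[`, "", 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      stop("XYZ parse error in frame starting at line ", i,
           ": non-numeric coordinate", call. = FALSE)
    }
    if (is.null(names_ref)) {
      names_ref <- nm
    } else if (length(nm) != length(names_ref)) {
      stop("XYZ structure error: inconsistent bead count across frames",
           call. = FALSE)
    }
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm)) {
      as.numeric(sub("t=\\s*", "", tm))
    } else NA_real_)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nb
  }
  if (!length(frames)) stop("XYZ parse error: no frames found", call. = FALSE)
  if (all(is.na(times))) times <- (seq_along(frames) - 1) * timestep
  coords <- array(NA_real_, dim = c(length(frames), length(names_ref), 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  topo <- build_topology(names_ref, rep("XXX", length(names_ref)),
                         rep("X", length(names_ref)), lipid_registry)
  trajectory(topo, coords, times = times)
}

# ---------------------------------------------------------------------------
# Writers

#' Write a trajectory to disk
#'
#' PDB output is multi-model (`MODEL`/`ENDMDL`), coordinates multiplied by
#' 10 (nm to Angstrom) and the leaflet label stored in the chain column
#' (`C`/`L`/`R`, `X` for unassigned). GRO and XYZ are written in nm with the
#' frame time in the title/comment line (`t= <ns>`), so they round-trip
#' times as well as positions; PDB round-trips positions to its fixed 1e-3 A
#' precision.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"pdb"`, `"gro"` or `"xyz"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("auto", "pdb", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro", xyz = "xyz",
                     stop("cannot infer format from '", ext, "'",
                          call. = FALSE))
  }
  topo <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  if (format == "pdb") {
    serial <- ((seq_len(nrow(topo)) - 1L) %% 99999L) + 1L
    resseq <- ((topo$index) %% 9999L) + 1L
    chain <- leaflet_to_code(topo$leaflet)
    for (k in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      xyzA <- frame_coords(traj, k) * 10
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial, substr(topo$name, 1, 4), substr(topo$species, 1, 4),
        chain, resseq, xyzA[, 1], xyzA[, 2], xyzA[, 3], 1, 0), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else if (format == "gro") {
    resnm <- paste0(substr(topo$species, 1, 3), "_",
                    leaflet_to_code(topo$leaflet))
    resid <- ((topo$index) %% 99999L) + 1L
    atid <- ((seq_len(nrow(topo)) - 1L) %% 99999L) + 1L
    for (k in seq_len(nf)) {
      writeLines(sprintf("memshape frame %d t= %.10g", k, traj$times[k]), con)
      writeLines(sprintf("%5d", nrow(topo)), con)
      xyz <- frame_coords(traj, k)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         resid, resnm, substr(topo$name, 1, 5), atid,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", 0, 0, 0), con)
    }
  } else {
    for (k in seq_len(nf)) {
      writeLines(as.character(nrow(topo)), con)
      writeLines(sprintf("memshape frame %d t= %.17g", k, traj$times[k]), con)
      xyz <- frame_coords(traj, k)
      writeLines(sprintf("%s %.17g %.17g %.17g", topo$name,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tabular output (TSV with a provenance comment line)

series_header <- function() {
  sprintf("# memshape-kinetics v%s",
          as.character(utils::packageVersion("memshape")))
}

write_tsv_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(series_header(), con)
  fmt_col <- function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, fmt_col, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write an analysis table or series as TSV
#'
#' Writes a header comment line (`# memshape-kinetics v...`), a column
#' header, and full-precision values (`%.17g`); missing values (e.g.
#' censored entries) are written as the literal `NA`. The output round-trips
#' losslessly through [read_series()].
#'
#' @param x a [curvature_series()], [waiting_time_set()] or data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) UseMethod("write_series")

#' @export
write_series.data.frame <- function(x, path) write_tsv_table(x, path)

#' @export
write_series.curvature_series <- function(x, path) {
  write_tsv_table(as.data.frame(x), path)
}

#' @export
write_series.waiting_time_set <- function(x, path) {
  con <- file(path, "w")
  writeLines(c(series_header(),
               sprintf("#! horizon_ns=%.17g", x$horizon),
               if (!is.null(x$threshold))
                 sprintf("#! threshold=%.17g", x$threshold),
               if (!is.null(x$system_label) && nzchar(x$system_label))
                 sprintf("#! system=%s", x$system_label)), con)
  close(con)
  tmp <- tempfile()
  write_tsv_table(data.frame(time_ns = x$times, censored = x$censored), tmp)
  body <- readLines(tmp)
  unlink(tmp)
  cat(body[-1], file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_series()]
#' @param path input path.
#' @return data frame (metadata comment lines are skipped).
#' @export
read_series <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a waiting-time table written by [write_series()]
#' @param path input path.
#' @return a [waiting_time_set()].
#' @export
read_waiting_times <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#! ", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#! ", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#! ", key, "="), "", hit[1]) else NULL
  }
  df <- read_series(path)
  horizon <- get_meta("horizon_ns")
  if (is.null(horizon)) horizon <- max(df$time_ns)
  thr <- get_meta("threshold")
  waiting_time_set(times = df$time_ns,
                   censored = as.logical(df$censored),
                   horizon = as.numeric(horizon),
                   threshold = if (!is.null(thr)) as.numeric(thr) else NULL,
                   system_label = get_meta("system") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
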