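# Amphipathic-helix descriptors: mean hydrophobicity, hydrophobic moment
# (Eisenberg construction), net charge, and helical-wheel geometry.

# Bundled hydrophobicity scales. The Eisenberg consensus scale is the
# common default of helical-wheel tools; Kyte-Doolittle is provided as an
# alternative. Outputs always carry the scale name: values from different
# scales are not comparable.
hydrophobicity_scales <- list(
  eisenberg = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
  kyte_doolittle = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
)

#' Bundled hydrophobicity scale names
#' @return character vector of scale names usable in [helix_profile()].
#' @export
list_hydrophobicity_scales <- function() names(hydrophobicity_scales)

#' Amphipathic-helix profile of a peptide
#'
#' Computes, for a sequence laid out on an ideal helical wheel with
#' `periodicity_deg` degrees per residue (100 degrees for an alpha helix):
#'
#' * `mean_hydrophobicity` — mean of the per-residue scale values;
#' * `hydrophobic_moment` — the Eisenberg vector construction
#'   `|sum_n h_n (cos(n d), sin(n d))| / N` (per-residue normalized so
#'   peptides of different lengths are comparable; the unnormalized sum is
#'   returned as `moment_sum`);
#' * `net_charge` — `count(R, K, H) - count(D, E)`, with histidine counted
#'   as positive;
#' * `wheel_angles` — the wheel angle of each residue,
#'   `(i * periodicity_deg) mod 360` for `i = 0 .. N-1`.
#'
#' @param sequence one-letter amino-acid string (standard 20 letters).
#' @param scale a bundled scale name (see
#'   [list_hydrophobicity_scales()]) or a named numeric vector over the 20
#'   amino acids.
#' @param periodicity_deg helical periodicity in degrees per residue.
#' @return object of class `"helix_profile"`.
#' @export
helix_profile <- function(sequence, scale = "eisenberg",
                          periodicity_deg = 100) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (is.character(scale)) {
    if (!scale %in% names(hydrophobicity_scales)) {
      stop("unknown scale '", scale, "'; bundled scales: ",
           paste(names(hydrophobicity_scales), collapse = ", "),
           call. = FALSE)
    }
    scale_name <- scale
    scale_values <- hydrophobicity_scales[[scale]]
  } else {
    scale_name <- "custom"
    scale_values <- scale
  }
  bad <- which(!aa %in% names(scale_values))
  if (length(bad)) {
    stop("unknown residue '", aa[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  h <- unname(scale_values[aa])
  n <- length(aa)
  delta <- periodicity_deg * pi / 180
  ang <- (seq_len(n) - 1) * delta
  mx <- sum(h * cos(ang))
  my <- sum(h * sin(ang))
  moment_sum <- sqrt(mx^2 + my^2)
  structure(list(
    sequence = paste(aa, collapse = ""),
    scale_name = scale_name,
    mean_hydrophobicity = mean(h),
    hydrophobic_moment = moment_sum / n,
    moment_sum = moment_sum,
    net_charge = sum(aa %in% c("R", "K", "H")) - sum(aa %in% c("D", "E")),
    periodicity_deg = periodicity_deg,
    wheel_angles = ((seq_len(n) - 1) * periodicity_deg) %% 360
  ), class = "helix_profile")
}

#' @export
print.helix_profile <- function(x, ...) {
  cat(sprintf(
    "<helix_profile> %d aa (%s scale): <H>=%.3f, muH=%.3f, charge=%+d\n",
    nchar(x$sequence), x$scale_name, x$mean_hydrophobicity,
    x$hydrophobic_moment, x$net_charge))
  invisible(x)
}

#' Helix profiles for every sequence of a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @param scale,periodicity_deg see [helix_profile()].
#' @return data frame with one row per sequence: `name`, `length`,
#'   `mean_hydrophobicity`, `hydrophobic_moment`, `moment_sum`,
#'   `net_charge`, `scale`.
#' @export
helix_profiles_fasta <- function(path, scale = "eisenberg",
                                 periodicity_deg = 100) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  rows <- lapply(seq_along(seqs), function(i) {
    p <- helix_profile(as.character(seqs[[i]]), scale, periodicity_deg)
    data.frame(name = names(seqs)[i], length = nchar(p$sequence),
               mean_hydrophobicity = p$mean_hydrophobicity,
               hydrophobic_moment = p$hydrophobic_moment,
               moment_sum = p$moment_sum, net_charge = p$net_charge,
               scale = p$scale_name, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
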