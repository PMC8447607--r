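# Shared data model and file round-trips.

test_that("trajectory construction enforces the data-model invariants", {
  topo <- data.frame(index = 0:2, name = "PO4", entity_kind = "lipid",
                     species = "DMPC", role = "head",
                     leaflet = "cytoplasmic", stringsAsFactors = FALSE)
  coords <- array(rnorm(2 * 3 * 3), dim = c(2, 3, 3))
  tr <- trajectory(topo, coords, times = c(0, 1))
  expect_s3_class(tr, "trajectory")
  expect_equal(n_frames(tr), 2)
  expect_equal(n_beads(tr), 3)

  expect_error(trajectory(topo, coords, times = c(1, 0)), "increasing")
  expect_error(trajectory(topo, coords, times = c(0, 1, 2)), "frames")
  bad <- coords; bad[1, 1, 1] <- NA
  expect_error(trajectory(topo, bad, times = c(0, 1)), "finite")
  topo_dup <- topo; topo_dup$index <- c(0, 0, 2)
  expect_error(trajectory(topo_dup, coords, times = c(0, 1)), "unique")
  expect_error(trajectory(topo, coords, times = c(0, 1.5), timestep = 1),
               "timestep")
})

test_that("multi-model PDB files round-trip and parse with correct counts", {
  p <- bicelle_params(seed = 3, horizon = 3)
  tr <- generate_bicelle_trajectory(p)$trajectory
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(n_frames(back), n_frames(tr))
  expect_equal(n_beads(back), n_beads(tr))
  # PDB stores 1e-3 A; positions round-trip to 1e-3 nm
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3)
  expect_equal(back$topology$species, tr$topology$species)
  expect_equal(back$topology$leaflet, tr$topology$leaflet)
  expect_equal(back$topology$entity_kind, tr$topology$entity_kind)
  expect_equal(back$topology$role, tr$topology$role)

  # minimal 2-model, 4-atom file parses to 2 frames x 4 beads
  mini <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("MODEL     1",
             sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     1:4, "PO4", "DMPC", "C", 1:4, 1:4, 0, 0, 1, 0),
             "ENDMDL", "MODEL     2",
             sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                     1:4, "PO4", "DMPC", "C", 1:4, 2:5, 0, 0, 1, 0),
             "ENDMDL", "END")
  writeLines(lines, mini)
  two <- read_trajectory(mini)
  expect_equal(n_frames(two), 2)
  expect_equal(n_beads(two), 4)
})

test_that("XYZ files round-trip exactly and default times to zero", {
  set.seed(11)
  coords <- array(rnorm(1 * 10 * 3), dim = c(1, 10, 3))
  tr <- protein_traj(coords, times = 0)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(n_frames(back), 1)
  expect_equal(n_beads(back), 10)
  expect_identical(back$times, 0)
  expect_equal(back$coords, tr$coords, tolerance = 0)  # full precision
})

test_that("GRO series carry frame times and reject decreasing ones", {
  p <- bicelle_params(seed = 3, horizon = 2, n_long_lipids = 60,
                      n_rim_lipids = 10)
  tr <- generate_bicelle_trajectory(p)$trajectory
  path <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$times, tr$times)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3)
  expect_equal(back$topology$leaflet, tr$topology$leaflet)

  # decreasing t= comments are a structure error
  lines <- readLines(path)
  lines <- gsub("t= 1", "t= -5", lines, fixed = TRUE)
  bad <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines, bad)
  expect_error(read_trajectory(bad), "strictly increasing")
})

test_that("select_beads filters stably, idempotently and commutes with frame subsetting", {
  p <- bicelle_params(seed = 5, horizon = 4)
  tr <- generate_bicelle_trajectory(p)$trajectory
  dm <- select_beads(tr, 'species == "DMPC"')
  expect_true(all(dm$topology$species == "DMPC"))
  expect_equal(n_beads(dm), 300)
  heads <- select_beads(tr, 'role == "head"')
  expect_equal(n_beads(heads), 400)  # one head bead per lipid
  # identity and idempotence
  expect_equal(select_beads(tr, rep(TRUE, n_beads(tr)))$coords, tr$coords)
  expect_equal(select_beads(dm, 'species == "DMPC"'), dm)
  # stable order by original index
  expect_true(!is.unsorted(dm$topology$index))
  # commutes with frame subsetting
  a <- select_beads(subset_frames(tr, 2:3), 'leaflet == "rim"')
  b <- subset_frames(select_beads(tr, 'leaflet == "rim"'), 2:3)
  expect_equal(a, b)
  expect_error(select_beads(tr, 'species == "NOPE"'), "empty")
})

test_that("TSV series writing round-trips full precision and censored NA cells", {
  df <- data.frame(time_ns = c(1 / 3, pi, 1e-17),
                   H = c(0.1234567890123456, NA, -1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(df, path)
  expect_match(readLines(path, n = 1), "^# memshape-kinetics v")
  back <- read_series(path)
  expect_identical(back$time_ns, df$time_ns)
  expect_identical(back$H, df$H)

  # empty table: provenance + header only
  write_series(df[0, ], path)
  expect_length(readLines(path), 2)

  # waiting-time sets keep horizon/threshold metadata
  wts <- waiting_time_set(c(10, 20, 50, 50), c(FALSE, FALSE, TRUE, TRUE),
                          horizon = 50, threshold = 0.15,
                          system_label = "demo")
  write_series(wts, path)
  back <- read_waiting_times(path)
  expect_identical(back$times, wts$times)
  expect_identical(back$censored, wts$censored)
  expect_identical(back$horizon, wts$horizon)
  expect_identical(back$threshold, wts$threshold)

  # curvature series round-trip
  s <- curvature_series_new(0:5, sin(0:5) / 10, source = "r1")
  write_series(s, path)
  back <- read_series(path)
  expect_identical(back$H, s$H)
})
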