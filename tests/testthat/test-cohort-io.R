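make_manifest_df <- function() {
  # 22 controls and 18 patients at session 1, plus follow-ups for one
  # patient with the four-session longitudinal schedule
  rows <- rbind(
    data.frame(subject_id = sprintf("HC%02d", 1:22), group = "control",
               session = 1L, weeks = 0, data_path = "x.csv",
               motion = 0.04, score_motor = NA_real_),
    data.frame(subject_id = sprintf("SCI%02d", 1:18), group = "patient",
               session = 1L, weeks = 0, data_path = "x.csv",
               motion = 0.06, score_motor = 32),
    data.frame(subject_id = "SCI14", group = "patient", session = 2:4,
               weeks = c(2, 6, 25), data_path = "x.csv", motion = 0.05,
               score_motor = c(34, 36, 38)))
  rows
}

test_that("manifest reading validates and types the cohort design", {
  path <- tempfile(fileext = ".csv")
  write.csv(make_manifest_df(), path, row.names = FALSE, quote = FALSE)
  man <- read_manifest(path)
  expect_equal(nrow(man), 43L)
  expect_equal(sum(man$group == 1L & man$session_index == 1L), 18L)
  expect_equal(sum(man$group == -1L), 22L)
  sci14 <- man[man$subject_id == "SCI14", ]
  expect_equal(sort(sci14$weeks), c(0, 2, 6, 25))
  expect_equal(sort(sci14$session_index), 1:4)
  expect_true("score_motor" %in% names(man))
})

test_that("manifest round-trips losslessly through write/read", {
  path <- tempfile(fileext = ".csv")
  write.csv(make_manifest_df(), path, row.names = FALSE, quote = FALSE)
  man <- read_manifest(path)
  path2 <- tempfile(fileext = ".tsv")
  write_manifest(man, path2)
  man2 <- read_manifest(path2)
  for (col in c("subject_id", "group", "session_index", "weeks",
                "data_path", "motion", "score_motor"))
    expect_equal(man2[[col]], man[[col]], info = col)
})

test_that("manifest invariant violations error with context", {
  df <- make_manifest_df()
  path <- tempfile(fileext = ".csv")

  bad <- df; bad$group[3] <- "zebra"
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_manifest(path), "unknown group token 'zebra' in manifest row 3")

  bad <- rbind(df, df[1, ])
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_manifest(path), "duplicate \\(subject, session\\)")

  bad <- df; bad$session[1] <- 2L
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_manifest(path), "scanned only once|contiguous")

  bad <- df[df$subject_id != "SCI14" | df$session != 2, ]
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_manifest(path), "not contiguous")

  # header-only file gives an empty, well-typed record set
  writeLines("subject_id,group,session,data_path", path)
  expect_equal(nrow(read_manifest(path)), 0L)
})

test_that("motion QC flags but never drops sessions", {
  df <- make_manifest_df()
  path <- tempfile(fileext = ".csv")
  df$motion[1] <- 3.1
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  man <- flag_motion(read_manifest(path))
  expect_equal(nrow(man), nrow(df))
  expect_identical(which(man$motion_flag), 1L)
})

test_that("ROI extraction averages labeled voxels per timepoint", {
  dims <- c(4, 4, 3); Tn <- 5
  lab <- array(0L, dims)
  lab[1, 1, 1] <- 1L                      # single voxel ROI
  lab[2, 1, 1] <- 2L; lab[3, 1, 1] <- 2L  # two-voxel ROI
  img <- array(0, c(dims, Tn))
  img[1, 1, 1, ] <- c(7, 8, 9, 10, 11)
  img[2, 1, 1, ] <- c(1, 2, 3, 4, 5)
  img[3, 1, 1, ] <- c(3, 4, 5, 6, 7)
  ts <- extract_roi_timeseries(img, lab)
  expect_equal(ts$region_labels, c("1", "2"))
  expect_equal(unname(ts$series[, "1"]), c(7, 8, 9, 10, 11))
  expect_equal(unname(ts$series[1:3, "2"]), c(2, 3, 4))

  # spatially constant image -> every ROI column equals the constant
  img5 <- array(5, c(dims, Tn))
  ts5 <- extract_roi_timeseries(img5, lab)
  expect_true(all(ts5$series == 5))
})

test_that("ROI extraction conserves the global mean over a partition", {
  set.seed(5)
  dims <- c(5, 4, 3); Tn <- 6
  lab <- array(sample(1:4, prod(dims), replace = TRUE), dims)  # full partition
  img <- array(rnorm(prod(dims) * Tn), c(dims, Tn))
  ts <- extract_roi_timeseries(img, lab)
  counts <- as.vector(table(lab))
  weighted <- drop(ts$series %*% counts) / sum(counts)
  global <- apply(img, 4, mean)
  expect_equal(weighted, global, tolerance = 1e-10)
})

test_that("ROI extraction commutes with label renumbering", {
  set.seed(6)
  dims <- c(4, 4, 2); Tn <- 4
  lab <- array(sample(0:3, prod(dims), replace = TRUE), dims)
  img <- array(rnorm(prod(dims) * Tn), c(dims, Tn))
  ts <- extract_roi_timeseries(img, lab)
  # remap 1,2,3 -> 30,10,20: columns reorder by ascending new label
  remap <- c(30L, 10L, 20L)
  lab2 <- array(0L, dims); for (l in 1:3) lab2[lab == l] <- remap[l]
  ts2 <- extract_roi_timeseries(img, lab2)
  expect_equal(ts2$region_labels, c("10", "20", "30"))
  expect_equal(unname(ts2$series), unname(ts$series[, c(2, 3, 1)]))
})

test_that("ROI extraction resamples a coarser atlas by nearest neighbor", {
  # functional grid: 4x4x2 at 1mm; atlas grid: 2x2x1 at 2mm covering the
  # same field of view, so each atlas voxel maps onto a 2x2x2 block
  dims <- c(4, 4, 2); Tn <- 3
  img <- array(0, c(dims, Tn))
  for (t in seq_len(Tn)) img[, , , t] <- t * array(rep(1:4, each = 1), dims)
  aff_f <- diag(4)
  aff_l <- diag(c(2, 2, 2, 1)); aff_l[1:3, 4] <- 0.5
  lab <- array(c(1L, 2L, 3L, 4L), c(2, 2, 1))
  ts <- extract_roi_timeseries(img, lab, image_affine = aff_f,
                               label_affine = aff_l)
  expect_equal(ts$region_labels, c("1", "2", "3", "4"))
  expect_equal(nrow(ts$series), Tn)
  # each ROI has 8 functional voxels (2x2x2)
  same_grid <- extract_roi_timeseries(
    img, array(rep(rep(1:4, each = 2), length.out = prod(dims)), dims),
    image_affine = aff_f, label_affine = aff_f)
  expect_equal(dim(same_grid$series), c(Tn, 4L))
  # a label vanishing after alignment is an error naming it
  lab_far <- lab
  aff_far <- aff_l; aff_far[1:3, 4] <- 100
  expect_error(extract_roi_timeseries(img, lab_far, image_affine = aff_f,
                                      label_affine = aff_far),
               "zero voxels after alignment: 1, 2, 3, 4")
})

test_that("NIfTI round-trip feeds extraction", {
  dims <- c(3, 3, 2); Tn <- 4
  img <- array(rnorm(prod(dims) * Tn), c(dims, Tn))
  lab <- array(rep(1:2, length.out = prod(dims)), dims)
  fi <- tempfile(fileext = ".nii.gz"); fl <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), fi)
  RNifti::writeNifti(RNifti::asNifti(lab), fl)
  ts <- extract_roi_timeseries(fi, fl)
  direct <- extract_roi_timeseries(img, lab)
  expect_equal(unname(ts$series), unname(direct$series), tolerance = 1e-6)
})

test_that("time-series and network tables round-trip", {
  set.seed(7)
  ts <- matrix(rnorm(20 * 4), 20)
  colnames(ts) <- paste0("R", 1:4)
  p1 <- tempfile(fileext = ".csv")
  write_timeseries_csv(ts, p1)
  back <- read_timeseries_csv(p1)
  expect_equal(unname(back$series), unname(ts), tolerance = 1e-12)
  expect_equal(back$region_labels, colnames(ts))

  net <- pearson_connectivity(ts)
  p2 <- tempfile(fileext = ".csv")
  write_network_csv(net, p2)
  net2 <- read_network_csv(p2)
  expect_equal(net2$edges, net$edges, tolerance = 1e-12)
})

test_that("model bundles round-trip through JSON", {
  co <- small_cohort(seed = 3)
  fs <- first_session_data(co)
  m <- fit_discriminant(fs$X, fs$y)
  bundle <- model_bundle(m$sig, m$hyperplane, co$region_labels, seed = 3)
  path <- tempfile(fileext = ".json")
  write_model(bundle, path)
  back <- read_model(path)
  expect_identical(back$sig$positions, bundle$sig$positions)
  expect_equal(back$hyperplane$w, bundle$hyperplane$w, tolerance = 1e-12)
  expect_equal(back$hyperplane$b, bundle$hyperplane$b, tolerance = 1e-12)
  expect_equal(back$hyperplane$C, 1)
  # a fresh network scores identically under the round-tripped model
  v <- extract_features(co$edges[1, ], m$sig)
  expect_equal(signed_distance(v, back$hyperplane),
               signed_distance(v, m$hyperplane), tolerance = 1e-12)

  # schema guard and consistency guard
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- "9.9"
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(x, p2, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(p2), "schema version")
  x$schema_version <- "1.0"
  x$hyperplane$w <- x$hyperplane$w[-1]
  jsonlite::write_json(x, p2, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(p2), "does not match significant set")
  expect_error(model_bundle(m$sig, structure(list(w = 1, b = 0, C = 1),
                                             class = "rehab_hyperplane")),
               "does not match")
})

test_that("a simulated cohort round-trips through disk and load_cohort", {
  co <- small_cohort(seed = 9, n_controls = 4, n_patients = 3, n_long = 0)
  dir <- tempfile()
  write_cohort(co, dir)
  loaded <- load_cohort(file.path(dir, "manifest.csv"))
  expect_equal(dim(loaded$edges), dim(co$edges))
  expect_equal(unname(loaded$edges), unname(co$edges), tolerance = 1e-6)
  expect_equal(loaded$manifest$group, co$manifest$group)
  expect_equal(loaded$manifest$session_index, co$manifest$session_index)
})
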