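#' ROI time-series object
#'
#' @param series T x k numeric matrix (timepoints x regions).
#' @param region_labels ordered identifiers for the k regions.
#' @param subject_id,session_index optional back-references.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(series, region_labels = NULL,
                           subject_id = NA_character_,
                           session_index = NA_integer_) {
  series <- as.matrix(series)
  storage.mode(series) <- "double"
  if (nrow(series) < 3L) stop("need at least 3 timepoints")
  if (is.null(region_labels)) {
    region_labels <- colnames(series)
    if (is.null(region_labels)) region_labels <- as.character(seq_len(ncol(series)))
  }
  if (length(region_labels) != ncol(series))
    stop("region_labels length does not match number of columns")
  all_missing <- apply(series, 2L, function(x) all(is.na(x)))
  if (any(all_missing))
    stop("region(s) entirely missing: ",
         paste(region_labels[all_missing], collapse = ", "))
  colnames(series) <- region_labels
  structure(list(series = series, region_labels = as.character(region_labels),
                 subject_id = subject_id, session_index = session_index),
            class = "roi_timeseries")
}

.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

.group_to_code <- function(tok) {
  t <- tolower(trimws(as.character(tok)))
  code <- ifelse(t %in% c("patient", "+1", "1", "p", "sci"), 1L,
          ifelse(t %in% c("control", "-1", "hc", "c", "healthy"), -1L,
                 NA_integer_))
  code
}

#' Read a cohort manifest
#'
#' Reads a delimited (CSV/TSV) manifest with header columns `subject_id`,
#' `group`, `session`, `data_path`, plus optional `weeks`, `motion` (mean
#' head motion in mm) and any number of clinical score columns prefixed
#' `score_`. Group tokens `patient`/`+1` map to +1 and `control`/`-1`/`hc`
#' to -1.
#'
#' @param path manifest file path.
#' @return a data frame of session records with columns `subject_id`,
#'   `group` (integer +1/-1), `group_label`, `session_index`, `weeks`,
#'   `data_path`, `motion`, and any `score_*` columns. Missing optional
#'   values are `NA`; clinical scores are never imputed.
#' @details Validated invariants: groups are known tokens (unknown token
#'   errors with the offending row), (subject, session) pairs are unique,
#'   session indices per subject are contiguous from 1, and controls have
#'   exactly one session (the single-scan study design for healthy
#'   subjects).
#' @export
read_manifest <- function(path) {
  df <- .read_delim_auto(path)
  req <- c("subject_id", "group", "session", "data_path")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("manifest is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- data.frame(subject_id = character(), group = integer(),
                      group_label = character(), session_index = integer(),
                      weeks = numeric(), data_path = character(),
                      motion = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  code <- .group_to_code(df$group)
  if (anyNA(code)) {
    bad <- which(is.na(code))[1L]
    stop("unknown group token '", df$group[bad], "' in manifest row ", bad)
  }
  out <- data.frame(
    subject_id = as.character(df$subject_id),
    group = code,
    group_label = ifelse(code == 1L, "patient", "control"),
    session_index = as.integer(df$session),
    weeks = if ("weeks" %in% names(df)) as.numeric(df$weeks) else NA_real_,
    data_path = as.character(df$data_path),
    motion = if ("motion" %in% names(df)) as.numeric(df$motion) else NA_real_,
    stringsAsFactors = FALSE)
  for (sc in grep("^score_", names(df), value = TRUE))
    out[[sc]] <- as.numeric(df[[sc]])
  validate_manifest(out)
  out
}

#' Validate session-record invariants of a manifest
#' @param records a manifest data frame (see [read_manifest()]).
#' @return `records`, invisibly; errors on violation.
#' @export
validate_manifest <- function(records) {
  key <- paste(records$subject_id, records$session_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (subject, session): ", d)
  }
  if (any(records$session_index < 1L))
    stop("session indices must be >= 1")
  for (s in unique(records$subject_id)) {
    ses <- sort(records$session_index[records$subject_id == s])
    if (!identical(ses, seq_len(length(ses))))
      stop("sessions of subject ", s, " are not contiguous from 1: ",
           paste(ses, collapse = ","))
  }
  ctrl_multi <- records$group == -1L & records$session_index > 1L
  if (any(ctrl_multi))
    stop("control subject(s) with more than one session: ",
         paste(unique(records$subject_id[ctrl_multi]), collapse = ", "),
         " (healthy subjects are scanned only once in this design)")
  if (any(!is.na(records$weeks) & records$weeks < 0))
    stop("'weeks' must be >= 0")
  invisible(records)
}

#' Write a cohort manifest
#' @param records manifest data frame.
#' @param path output file; `.tsv` extension writes tab-separated,
#'   otherwise comma-separated.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  df <- records
  df$group <- df$group_label
  df$group_label <- NULL
  names(df)[names(df) == "session_index"] <- "session"
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag sessions exceeding head-motion thresholds
#'
#' Sessions whose user-supplied motion summaries exceed the thresholds are
#' flagged — never silently dropped; exclusion is the analyst's call.
#'
#' @param records manifest data frame with a `motion` column (mean
#'   translation, mm) and optionally `motion_rot` (degrees).
#' @param max_translation_mm,max_rotation_deg thresholds (defaults
#'   2.5 mm / 2 degrees).
#' @return `records` with a logical `motion_flag` column (`NA` motion is
#'   not flagged).
#' @export
flag_motion <- function(records, max_translation_mm = 2.5,
                        max_rotation_deg = 2) {
  flag <- !is.na(records$motion) & records$motion > max_translation_mm
  if ("motion_rot" %in% names(records))
    flag <- flag | (!is.na(records$motion_rot) &
                      records$motion_rot > max_rotation_deg)
  records$motion_flag <- flag
  records
}

#' Read/write an ROI time-series table
#'
#' T x k delimited table, header = region labels.
#' @param path file path.
#' @return for `read_timeseries_csv`, an `roi_timeseries`.
#' @export
read_timeseries_csv <- function(path) {
  df <- .read_delim_auto(path)
  roi_timeseries(as.matrix(df), region_labels = names(df))
}

#' @rdname read_timeseries_csv
#' @param ts an `roi_timeseries` or T x k matrix with column names.
#' @export
write_timeseries_csv <- function(ts, path) {
  m <- if (inherits(ts, "roi_timeseries")) ts$series else as.matrix(ts)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(m, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a labeled connectivity matrix
#'
#' k x k delimited table with a leading `region` column and region labels
#' as the remaining headers.
#' @param path file path.
#' @return for `read_network_csv`, a `connectivity_network`.
#' @export
read_network_csv <- function(path) {
  df <- .read_delim_auto(path)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(labs, colnames(m)))
    stop("row and column region labels disagree in ", path)
  connectivity_network(m, region_labels = labs)
}

#' @rdname read_network_csv
#' @param net a `connectivity_network`.
#' @export
write_network_csv <- function(net, path) {
  stopifnot(inherits(net, "connectivity_network"))
  df <- data.frame(region = net$region_labels, net$edges,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.as_nifti_array <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  aff <- tryCatch(structure(RNifti::xform(x), class = NULL),
                  error = function(e) NULL)
  list(data = unclass(as.array(x)), affine = aff)
}

# nearest-neighbor lookup of label values at the functional grid's voxel
# centers, mapping through the two affines (0-based voxel convention)
.resample_labels_nn <- function(lab, lab_affine, dim_func, func_affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dim_func[1L]) - 1L,
                               j = seq_len(dim_func[2L]) - 1L,
                               k = seq_len(dim_func[3L]) - 1L))
  world <- func_affine %*% rbind(t(idx), 1)
  vl <- solve(lab_affine) %*% world
  vl <- round(t(vl[1:3, , drop = FALSE]))
  out <- integer(nrow(vl))
  inb <- vl[, 1L] >= 0 & vl[, 1L] < dim(lab)[1L] &
         vl[, 2L] >= 0 & vl[, 2L] < dim(lab)[2L] &
         vl[, 3L] >= 0 & vl[, 3L] < dim(lab)[3L]
  out[inb] <- lab[cbind(vl[inb, 1L] + 1L, vl[inb, 2L] + 1L, vl[inb, 3L] + 1L)]
  array(out, dim = dim_func)
}

#' Extract region-mean time courses from a 4D image and a label volume
#'
#' Averages, at every timepoint, the functional-image voxels sharing each
#' positive integer label of the atlas volume. Columns are ordered by
#' ascending label value — the ordering that defines edge indices for the
#' whole cohort. If the atlas grid differs from the functional grid, the
#' label volume is resampled to the functional grid by nearest neighbor
#' through the two voxel-to-world affines (labels are never interpolated).
#'
#' @param image 4D array, NIfTI image, or path to a `.nii`/`.nii.gz` file.
#' @param labels 3D integer array, NIfTI image, or path (0 = background).
#' @param image_affine,label_affine 4x4 voxel-to-world affines; taken from
#'   the NIfTI headers when images are given, required for bare arrays on
#'   mismatched grids.
#' @param subject_id,session_index optional back-references.
#' @return an `roi_timeseries` (T x number-of-labels).
#' @details A label with zero voxels after alignment is an error listing
#'   the label — never a silent NaN column.
#' @export
extract_roi_timeseries <- function(image, labels, image_affine = NULL,
                                   label_affine = NULL,
                                   subject_id = NA_character_,
                                   session_index = NA_integer_) {
  im <- .as_nifti_array(image)
  lb <- .as_nifti_array(labels)
  img <- im$data
  if (length(dim(img)) != 4L) stop("functional image must be 4D")
  lab <- lb$data
  if (length(dim(lab)) != 3L) stop("label volume must be 3D")
  if (is.null(image_affine)) image_affine <- im$affine
  if (is.null(label_affine)) label_affine <- lb$affine
  dim3 <- dim(img)[1:3]
  lab_orig <- as.integer(round(lab))
  orig_labels <- sort(unique(lab_orig[lab_orig > 0L]))
  same_grid <- identical(as.integer(dim(lab)), as.integer(dim3)) &&
    (is.null(image_affine) || is.null(label_affine) ||
       max(abs(image_affine - label_affine)) < 1e-6)
  if (!same_grid) {
    if (is.null(image_affine) || is.null(label_affine))
      stop("label and image grids differ and affines are not available ",
           "for nearest-neighbor resampling")
    if (abs(det(label_affine)) < 1e-12) stop("label affine is singular")
    lab <- .resample_labels_nn(lab, label_affine, dim3, image_affine)
  }
  lab <- as.integer(round(lab))
  labs_present <- sort(unique(lab[lab > 0L]))
  if (length(orig_labels) == 0L)
    stop("label volume contains no positive labels")
  lost <- setdiff(orig_labels, labs_present)
  if (length(lost))
    stop("label(s) with zero voxels after alignment: ",
         paste(lost, collapse = ", "))
  Tn <- dim(img)[4L]
  nvox <- prod(dim3)
  mat <- matrix(img, nrow = nvox, ncol = Tn)
  labv <- lab
  keep <- labv > 0L
  sums <- rowsum(mat[keep, , drop = FALSE], group = labv[keep])
  counts <- as.vector(table(labv[keep]))
  series <- t(sums / counts)
  colnames(series) <- rownames(sums)
  roi_timeseries(series, region_labels = rownames(sums),
                 subject_id = subject_id, session_index = session_index)
}

#' Serialize / deserialize a trained model bundle
#'
#' A model bundle couples the significant set, the hyperplane (w, b, C)
#' and the cohort's region labels with provenance, in a versioned JSON
#' schema. Round-trips preserve edge indices exactly and floats to at
#' least 1e-12 relative error.
#'
#' @param sig a `significant_set`.
#' @param hyperplane a `rehab_hyperplane`.
#' @param region_labels the cohort's ordered region labels.
#' @param seed seed recorded as provenance (or `NA`).
#' @return for `model_bundle`, an object of class `model_bundle`.
#' @export
model_bundle <- function(sig, hyperplane, region_labels = NULL, seed = NA) {
  stopifnot(inherits(sig, "significant_set"),
            inherits(hyperplane, "rehab_hyperplane"))
  if (length(hyperplane$w) != length(sig$positions))
    stop("weight vector length (", length(hyperplane$w),
         ") does not match significant set size (", length(sig$positions), ")")
  structure(list(
    schema_version = "1.0",
    sig = sig, hyperplane = hyperplane,
    region_labels = region_labels,
    provenance = list(timestamp = format(Sys.time(), tz = "UTC"),
                      seed = seed,
                      software = paste0("rehabdist ",
                                        as.character(utils::packageVersion("rehabdist"))))),
    class = "model_bundle")
}

#' @rdname model_bundle
#' @param bundle a `model_bundle`.
#' @param path JSON file path.
#' @export
write_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  x <- list(
    schema_version = bundle$schema_version,
    significant_set = list(
      positions = bundle$sig$positions,
      alpha = bundle$sig$alpha,
      var_equal = bundle$sig$var_equal,
      n_edges = bundle$sig$n_edges,
      t = bundle$sig$t, p = bundle$sig$p),
    hyperplane = list(w = bundle$hyperplane$w, b = bundle$hyperplane$b,
                      C = bundle$hyperplane$C),
    region_labels = bundle$region_labels,
    provenance = bundle$provenance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname model_bundle
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || !identical(x$schema_version, "1.0"))
    stop("model file has schema version '", x$schema_version,
         "'; this build reads schema 1.0 only")
  sig <- structure(
    list(positions = as.integer(x$significant_set$positions),
         pairs = NULL,
         t = as.numeric(x$significant_set$t),
         p = as.numeric(x$significant_set$p),
         alpha = x$significant_set$alpha,
         var_equal = isTRUE(x$significant_set$var_equal),
         n_edges = as.integer(x$significant_set$n_edges)),
    class = "significant_set")
  ktry <- try(nodes_from_edges(sig$n_edges), silent = TRUE)
  if (!inherits(ktry, "try-error"))
    sig$pairs <- edge_index(ktry)[sig$positions, , drop = FALSE]
  w <- as.numeric(x$hyperplane$w)
  if (length(w) != length(sig$positions))
    stop("invalid model file: weight vector length (", length(w),
         ") does not match significant set size (", length(sig$positions), ")")
  hp <- structure(
    list(w = w, b = as.numeric(x$hyperplane$b), C = as.numeric(x$hyperplane$C),
         xi = NULL, objective = NA_real_, n_support = NA_integer_,
         labels = c(patient = 1, control = -1)),
    class = "rehab_hyperplane")
  bundle <- structure(
    list(schema_version = x$schema_version, sig = sig, hyperplane = hp,
         region_labels = x$region_labels, provenance = x$provenance),
    class = "model_bundle")
  bundle
}

#' Assemble a typed cohort from a manifest and per-session data files
#'
#' Reads every session's data file (an ROI time-series table or a
#' precomputed connectivity matrix; auto-detected, or forced via
#' `data_kind`), builds Pearson networks where needed, and returns the
#' flat edge matrix aligned with the manifest rows.
#'
#' @param manifest a manifest data frame or a path passed to
#'   [read_manifest()].
#' @param data_kind `"auto"`, `"timeseries"` or `"network"`.
#' @param base_dir directory that relative `data_path`s are resolved
#'   against (defaults to the manifest's directory when a path is given).
#' @param fisher apply the Fisher z-transform to every network.
#' @return a list of class `rehab_cohort`: `manifest`, `edges` (sessions x
#'   edges matrix, rows in manifest order), `region_labels`.
#' @export
load_cohort <- function(manifest, data_kind = c("auto", "timeseries", "network"),
                        base_dir = NULL, fisher = FALSE) {
  data_kind <- match.arg(data_kind)
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  validate_manifest(manifest)
  nets <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    p <- manifest$data_path[r]
    if (!is.null(base_dir) && !file.exists(p)) p <- file.path(base_dir, p)
    if (!file.exists(p)) stop("data file not found: ", manifest$data_path[r])
    kind <- data_kind
    if (kind == "auto") {
      df <- .read_delim_auto(p)
      kind <- if (names(df)[1L] == "region" &&
                  nrow(df) == ncol(df) - 1L) "network" else "timeseries"
    }
    net <- if (kind == "network") read_network_csv(p)
           else pearson_connectivity(read_timeseries_csv(p))
    net$subject_id <- manifest$subject_id[r]
    net$session_index <- manifest$session_index[r]
    if (fisher) net <- fisher_z(net)
    nets[[r]] <- net
  }
  labs <- nets[[1L]]$region_labels
  for (net in nets)
    if (!identical(net$region_labels, labs))
      stop("region labels differ across sessions; the parcellation must ",
           "be identical for every session of a cohort")
  edges <- do.call(rbind, lapply(nets, vectorize_edges))
  rownames(edges) <- paste(manifest$subject_id, manifest$session_index,
                           sep = "_s")
  structure(list(manifest = manifest, edges = edges, region_labels = labs),
            class = "rehab_cohort")
}
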