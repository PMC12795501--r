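## Readers, writers and the demo pipeline -------------------------------------

#' Write an RDM to CSV or JSON
#'
#' CSV: square matrix with a header row and a leading label column
#' (`vectorized = TRUE` writes the long form `label_i, label_j, value`).
#' JSON: labels, values, metric.
#'
#' @param x an [rdm].
#' @param path output path; format chosen by extension (`.csv` / `.json`).
#' @param vectorized write the long CSV form.
#' @export
write_rdm <- function(x, path, vectorized = FALSE) {
  stopifnot(inherits(x, "rdm"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(labels = x$labels, values = x$values,
                              metric = x$metric),
                         path, digits = NA, auto_unbox = TRUE)
  } else if (ext == "csv") {
    if (vectorized) {
      idx <- utils::combn(n_conditions(x), 2)
      df <- data.frame(label_i = x$labels[idx[1, ]],
                       label_j = x$labels[idx[2, ]], value = x$values)
      utils::write.csv(df, path, row.names = FALSE)
    } else {
      m <- as.matrix(x)
      utils::write.csv(data.frame(label = rownames(m), m, check.names = FALSE),
                       path, row.names = FALSE)
    }
  } else stop("unsupported RDM format: ", ext)
  invisible(path)
}

#' Read an RDM written by [write_rdm()]
#'
#' Square CSV input must be symmetric within `tol` (it is symmetrized);
#' larger asymmetries are an error.
#'
#' @param path file path (`.csv` square or long form, or `.json`).
#' @param metric metric tag to attach when the file does not carry one.
#' @param tol symmetry tolerance for square input.
#' @return an [rdm].
#' @export
read_rdm <- function(path, metric = NULL, tol = 1e-9) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(rdm(obj$values, obj$labels,
               metric = if (!is.null(metric)) metric else obj$metric))
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (identical(names(df)[1:3], c("label_i", "label_j", "value")) &&
      ncol(df) == 3) {
    labels <- unique(c(df$label_i, df$label_j))
    n <- length(labels)
    m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
    m[cbind(df$label_i, df$label_j)] <- df$value
    m[cbind(df$label_j, df$label_i)] <- df$value
    diag(m) <- 0
    if (any(is.na(m))) stop("vectorized RDM is missing pairs")
    return(rdm_from_matrix(m, labels, metric = metric %||% "unknown", tol = tol))
  }
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(!is.finite(m))) stop("non-finite values in RDM file")
  rownames(m) <- labels
  rdm_from_matrix(m, labels, metric = metric %||% "unknown", tol = tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trial table as a tab-separated file
#'
#' Columns (header mandatory): participant, reference, intruder, correct,
#' rt (ms).
#' @param trials trial data.frame.
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(as.data.frame(trials))
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  validate_trials(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Serialize shapes to JSON (family, vertices, transform state)
#' @param shapes named list of `quad`s.
#' @param path output path.
#' @export
write_shapes_json <- function(shapes, path) {
  obj <- lapply(shapes, function(q) list(
    family = q$family, vertices = unname(q$vertices),
    scale = q$scale, rotation_deg = q$rotation_deg,
    bottom_side = q$bottom_side))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shapes_json
#' @export
read_shapes_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(o)
    .quad(matrix(unlist(o$vertices), ncol = 2, byrow = FALSE),
          o$family, scale = o$scale, rotation_deg = o$rotation_deg))
}

#' Render shapes to a simple SVG file
#' @param shapes named list of `quad`s.
#' @param path output `.svg` path.
#' @param size cell size in px per shape.
#' @export
write_shapes_svg <- function(shapes, path, size = 120) {
  n <- length(shapes)
  w <- size * n
  poly <- function(q, off) {
    v <- q$vertices
    sc <- size * 0.35 / max(abs(v))
    pts <- paste(sprintf("%.2f,%.2f", off + size / 2 + sc * v[, 1],
                         size / 2 - sc * v[, 2]), collapse = " ")
    sprintf('<polygon points="%s" fill="none" stroke="white" stroke-width="2"/>', pts)
  }
  body <- paste(mapply(poly, shapes, size * (seq_len(n) - 1)), collapse = "\n")
  svg <- sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" style="background:black">\n%s\n</svg>',
    w, size, body)
  writeLines(svg, path)
  invisible(path)
}

#' Write a statistic volume as NIfTI (requires the RNifti package)
#' @param map 3D array.
#' @param path `.nii` / `.nii.gz` path.
#' @param voxel_size voxel edge in mm.
#' @export
write_volume <- function(map, path, voxel_size = 2) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("write_volume requires the RNifti package")
  img <- RNifti::asNifti(map, pixdim = rep(voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Run the demonstration pipelines on synthetic data
#'
#' Executes the behavioral pipeline (reference shapes -> feature RDM ->
#' simulated visual-search trials -> empirical RDM -> model regression ->
#' ordinal MDS) and, optionally, a scaled-down neural pipeline (simulated
#' oddball epochs -> time-resolved crossnobis RSA -> whitened model
#' comparison -> temporal cluster test), writing outputs and a provenance
#' report to `out_dir`.
#'
#' @param config list (or path to a JSON file) with any of: `seed` (1),
#'   `out_dir` (required), `n_participants` (50), `tolerance` (0.125),
#'   `neural` (FALSE), `n_channels` (16), `n_perm` (1024), `tmax` (0.5).
#'   Unknown keys are rejected.
#' @return invisible list of stage results; files are written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(seed = 1, out_dir = NULL, n_participants = 50,
                   tolerance = 0.125, neural = FALSE, n_channels = 16,
                   n_perm = 1024, tmax = 0.5)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  put <- function(f) { outs <<- c(outs, f); f }

  shapes <- make_reference_shapes()
  write_shapes_json(shapes, put(file.path(cfg$out_dir, "shapes.json")))
  ft <- feature_table(shapes, cfg$tolerance)
  utils::write.csv(ft, put(file.path(cfg$out_dir, "features.csv")),
                   row.names = FALSE)
  frdm <- feature_rdm(shapes, cfg$tolerance)
  write_rdm(frdm, put(file.path(cfg$out_dir, "feature_rdm.csv")))

  trials <- simulate_behavior(frdm, n_participants = cfg$n_participants,
                              seed = cfg$seed)
  write_trials(trials, put(file.path(cfg$out_dir, "trials.tsv")))
  emp <- empirical_rdm(trials)
  write_rdm(emp, put(file.path(cfg$out_dir, "empirical_rdm.csv")))
  ## control model: dissimilarity of raw vertex layouts (low-level baseline)
  ctrl <- vertex_control_rdm(shapes)
  reg <- rdm_regression(emp, list(features = frdm, vertex = ctrl))
  emb <- mds_embed(emp, seed = cfg$seed)
  proj <- project_property(emb$points, ft$score)
  result <- list(regression = reg$coefficients, r_squared = reg$r_squared,
                 mds_stress = emb$stress, projection = proj$coefficients)

  if (isTRUE(cfg$neural)) {
    spec <- sim_spec(list(A = ctrl, B = frdm), n_channels = cfg$n_channels,
                     tmin = -0.1, tmax = cfg$tmax,
                     regularity = ft$score)
    ep <- simulate_epochs(spec, seed = cfg$seed)
    series <- epoch_rdm_series(ep)
    sim <- compare_models_separately(series, list(A = ctrl, B = frdm))
    utils::write.csv(data.frame(time = ep$times, sim),
                     put(file.path(cfg$out_dir, "rsa_timecourse.csv")),
                     row.names = FALSE)
    result$rsa_peak <- apply(sim, 2, max)
  }

  prov <- list(package = "geomrep",
               version = as.character(utils::packageVersion("geomrep")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"),
               seed = cfg$seed, config = cfg[setdiff(names(cfg), "out_dir")],
               outputs = lapply(stats::setNames(outs, basename(outs)),
                                function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Low-level control RDM from vertex layouts
#'
#' Euclidean distance between mpd-normalized, centroid-aligned vertex
#' coordinate vectors, minimized over the 4 cyclic vertex orderings; a crude
#' image-level baseline model.
#' @param shapes named list of `quad`s.
#' @return an [rdm] with metric `"vertex-euclidean"`.
#' @export
vertex_control_rdm <- function(shapes) {
  norm_v <- function(q) {
    v <- .center_quad(q$vertices)
    v / mpd(v)
  }
  vs <- lapply(shapes, norm_v)
  n <- length(vs)
  idx <- utils::combn(n, 2)
  vals <- apply(idx, 2, function(p) {
    a <- vs[[p[1]]]; b <- vs[[p[2]]]
    min(vapply(0:3, function(k)
      sqrt(sum((a - b[(0:3 + k) %% 4 + 1, ])^2)), numeric(1)))
  })
  rdm(vals, names(shapes), metric = "vertex-euclidean")
}
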