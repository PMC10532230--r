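#' Benchmark configuration
#'
#' Describes one evaluation run: where the in-distribution train and test
#' volumes live, a named set of OOD challenges, the detector and its
#' settings. Each volume source may be either a directory of 3D NIfTI
#' files or an in-memory list of `Volume`s (lists of `MaskVolume`s for the
#' `"volume"` baseline).
#'
#' @param id_train,id_test ID train / test source (directory or list).
#' @param ood_challenges named list of OOD sources (directories or lists).
#' @param method `"ihf"` or `"volume"` (predicted-volume baseline; sources
#'   must then be masks).
#' @param ihf an [ihf_config()] (ignored for the baseline).
#' @param preprocess a [preprocess_config()].
#' @param tpr ID acceptance rate for the FPR metric (default 0.95).
#' @return A `challenge_config`.
#' @export
challenge_config <- function(id_train, id_test, ood_challenges,
                             method = c("ihf", "volume"),
                             ihf = ihf_config(),
                             preprocess = preprocess_config(),
                             tpr = 0.95) {
  method <- match.arg(method)
  stopifnot(is.list(ood_challenges), length(ood_challenges) >= 1,
            !is.null(names(ood_challenges)),
            !anyDuplicated(names(ood_challenges)))
  structure(list(id_train = id_train, id_test = id_test,
                 ood_challenges = ood_challenges, method = method,
                 ihf = ihf, preprocess = preprocess, tpr = tpr),
            class = "challenge_config")
}

load_source <- function(src, reader = read_volume, what = "volume source") {
  if (is.character(src)) {
    stopifnot(length(src) == 1L)
    files <- sort(list.files(src, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (length(files) == 0L) stop("empty ", what, ": ", src)
    lapply(files, function(f)
      tryCatch(reader(f), error = function(e)
        stop("failed to read '", f, "': ", conditionMessage(e))))
  } else if (is.list(src)) {
    if (length(src) == 0L) stop("empty ", what)
    src
  } else stop("a ", what, " must be a directory path or a list")
}

#' Run one OOD detection benchmark
#'
#' Fits the configured detector once on the ID training source, scores the
#' ID test source once, then evaluates every OOD challenge against those
#' shared ID test scores -- so a single acceptance threshold governs all
#' challenges, as when one ID test set serves a whole modality. Returns a
#' per-challenge table of FPR at the configured TPR and AUROC, with the
#' overall arithmetic mean row, plus an audit log of the threshold and
#' sample counts.
#'
#' @param config a [challenge_config()].
#' @return A `benchmark_report`: list with `table` (data.frame: challenge,
#'   fpr_at_95tpr, auroc), `averages`, `log` (tau, n_id, n_ood per
#'   challenge) and `id_scores`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "challenge_config"))
  if (config$method == "ihf") {
    train <- load_source(config$id_train, read_volume, "id_train")
    id_test <- load_source(config$id_test, read_volume, "id_test")
    ref <- fit_reference(train, config$ihf, config$preprocess)
    scorer <- function(vols) ihf_score_all(ref, vols)
  } else {
    train <- load_source(config$id_train, read_mask, "id_train")
    id_test <- load_source(config$id_test, read_mask, "id_test")
    ref <- fit_volume_reference(train)
    scorer <- function(masks)
      volume_score(ref, vapply(masks, prediction_volume, numeric(1)))
  }
  id_scores <- scorer(id_test)
  tau <- sort(id_scores)[ceiling(config$tpr * length(id_scores))]
  reader <- if (config$method == "ihf") read_volume else read_mask
  rows <- lapply(names(config$ood_challenges), function(nm) {
    ood <- load_source(config$ood_challenges[[nm]], reader, paste0("challenge '", nm, "'"))
    ood_scores <- scorer(ood)
    cbind(data.frame(challenge = nm),
          evaluate_challenge(id_scores, ood_scores, config$tpr),
          data.frame(tau = tau, n_id = length(id_scores), n_ood = length(ood)))
  })
  tab <- do.call(rbind, rows)
  averages <- data.frame(fpr_at_95tpr = mean(tab$fpr_at_95tpr),
                         auroc = mean(tab$auroc))
  structure(list(table = tab[, c("challenge", "fpr_at_95tpr", "auroc")],
                 averages = averages,
                 log = tab[, c("challenge", "tau", "n_id", "n_ood")],
                 id_scores = id_scores, reference = ref),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("mean: FPR@95TPR = %.3f, AUROC = %.3f\n",
              x$averages$fpr_at_95tpr, x$averages$auroc))
  invisible(x)
}

#' Severity sweep of the synthetic corruptions
#'
#' Corrupts copies of the ID test volumes at each (kind, level) cell and
#' measures the FPR of a fitted IHF reference against the shared ID-test
#' threshold. More heavily distorted copies should be easier to reject,
#' so FPR is expected to fall as the level rises.
#'
#' @param ref a fitted `ihf_reference`.
#' @param id_test list of raw ID test `Volume`s (or a directory).
#' @param kinds character vector of corruption kinds.
#' @param levels integer severity levels (subset of 1:5).
#' @param seeds integer seeds, recycled over the test volumes; seed i is
#'   used for volume i within every cell, pairing cells across levels.
#' @param tpr ID acceptance rate (default 0.95).
#' @return data.frame with columns `kind`, `level`, `fpr_at_95tpr`.
#' @export
severity_sweep <- function(ref, id_test,
                           kinds = c("local_noise", "elastic", "kspace",
                                     "anisotropy", "ghosting", "motion"),
                           levels = 1:5, seeds = seq_along(id_test),
                           tpr = 0.95) {
  stopifnot(inherits(ref, "ihf_reference"), all(levels %in% 1:5))
  id_test <- load_source(id_test, read_volume, "id_test")
  seeds <- rep_len(seeds, length(id_test))
  id_scores <- ihf_score_all(ref, id_test)
  cells <- expand.grid(kind = kinds, level = levels, stringsAsFactors = FALSE)
  fpr <- mapply(function(kind, level) {
    ood <- lapply(seq_along(id_test), function(i)
      corrupt_volume(id_test[[i]], kind, level, seeds[i]))
    fpr_at_tpr(score_set(id_scores, ihf_score_all(ref, ood)), tpr)
  }, cells$kind, cells$level)
  data.frame(kind = cells$kind, level = cells$level, fpr_at_95tpr = fpr)
}

#' Pairwise Fechner correlation audit between methods
#'
#' Given per-challenge result vectors (e.g. FPR across the same ordered
#' challenges) for two or more methods, returns the symmetric matrix of
#' pairwise Fechner correlations with a unit diagonal. Weak off-diagonal
#' correlation indicates the methods exploit different features.
#'
#' @param results named list (or data.frame columns) of equal-length
#'   numeric vectors, one per method.
#' @return Symmetric correlation matrix with method names.
#' @export
fechner_audit <- function(results) {
  results <- as.list(results)
  stopifnot(length(results) >= 2, !is.null(names(results)))
  n <- length(results[[1]])
  if (!all(vapply(results, length, integer(1)) == n))
    stop("all result vectors must have equal length")
  k <- length(results)
  M <- diag(1, k)
  dimnames(M) <- list(names(results), names(results))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- fechner_correlation(results[[i]], results[[j]])
    M[i, j] <- r; M[j, i] <- r
  }
  M
}

#' Write a benchmark report to CSV and Markdown
#'
#' @param report a `benchmark_report` from [run_benchmark()].
#' @param csv_path,md_path destination paths (either may be `NULL`).
#' @return Invisibly, the Markdown lines.
#' @export
write_benchmark_report <- function(report, csv_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "benchmark_report"))
  tab <- report$table
  if (!is.null(csv_path)) {
    out <- rbind(tab, data.frame(challenge = "mean",
                                 fpr_at_95tpr = report$averages$fpr_at_95tpr,
                                 auroc = report$averages$auroc))
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  fmt <- function(ch, f, a) sprintf("| %s | %.3f | %.3f |", ch, f, a)
  md <- c("| challenge | FPR@95TPR | AUROC |", "|---|---|---|",
          mapply(fmt, tab$challenge, tab$fpr_at_95tpr, tab$auroc),
          fmt("**mean**", report$averages$fpr_at_95tpr, report$averages$auroc))
  if (!is.null(md_path)) writeLines(md, md_path)
  invisible(md)
}

#' Save / load a fitted IHF reference
#'
#' Serialises the full detector state (reducer, reduced training
#' embeddings, moments, configs) to a single JSON file with a format
#' version, and restores it. The Cholesky factor is recomputed on load.
#'
#' @param ref an `ihf_reference`.
#' @param path destination / source file.
#' @return `save_reference`: `path` invisibly; `load_reference`: the
#'   restored `ihf_reference`.
#' @export
save_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ihf_reference"))
  obj <- list(
    format_version = 1L,
    config = unclass(ref$config),
    preprocess_config = unclass(ref$preprocess_config),
    reducer = if (is.null(ref$reducer)) NULL else list(
      center = ref$reducer$center,
      basis = as.vector(ref$reducer$basis),
      basis_dim = dim(ref$reducer$basis),
      explained_variance_ratio = ref$reducer$explained_variance_ratio),
    train_reduced = as.vector(ref$train_reduced),
    train_dim = dim(ref$train_reduced),
    mean = ref$mean,
    covariance = as.vector(ref$covariance),
    cov_dim = dim(ref$covariance))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null"),
             path)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  if (!identical(as.integer(obj$format_version), 1L))
    stop("unsupported reference format version")
  cfg <- do.call(ihf_config, obj$config[c("m", "v", "use_pca", "scorer")])
  pp <- do.call(preprocess_config, obj$preprocess_config[
    c("target_spacing", "modality", "ct_window", "mri_percentiles")])
  reducer <- NULL
  if (!is.null(obj$reducer)) {
    reducer <- structure(list(
      center = as.numeric(obj$reducer$center),
      basis = matrix(as.numeric(obj$reducer$basis),
                     nrow = obj$reducer$basis_dim[1]),
      explained_variance_ratio = obj$reducer$explained_variance_ratio),
      class = "ihf_reducer")
  }
  Z <- matrix(as.numeric(obj$train_reduced), nrow = obj$train_dim[1])
  Sigma <- matrix(as.numeric(obj$covariance), nrow = obj$cov_dim[1])
  reference_from_moments(reducer, Z, as.numeric(obj$mean), Sigma, cfg, pp)
}
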