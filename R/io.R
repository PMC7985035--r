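#' Read a survival table
#'
#' Delimited text (TSV by default; comma auto-detected) with header
#' columns `sample`, `time`, `status`. Status must be coded 0 (censored)
#' / 1 (event); the 1/2 dialect used by some tools is rejected with a
#' message rather than silently recoded. Duplicate sample ids and missing
#' or non-positive times are errors.
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `time`, `status`.
#' @export
read_survival_table <- function(path) {
  tab <- .read_delim(path)
  need <- c("sample", "time", "status")
  miss <- setdiff(need, tolower(names(tab)))
  if (length(miss))
    stop("survival table must have header columns sample, time, status; ",
         "missing: ", paste(miss, collapse = ", "), call. = FALSE)
  names(tab) <- tolower(names(tab))
  tab <- tab[need]
  tab$sample <- as.character(tab$sample)
  dup <- tab$sample[duplicated(tab$sample)]
  if (length(dup))
    stop("duplicated sample id(s) in survival table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!is.numeric(tab$time) || !is.numeric(tab$status))
    stop("time and status columns must be numeric", call. = FALSE)
  if (all(tab$status %in% c(1, 2)) && any(tab$status == 2))
    stop("status appears to use the 1/2 coding; recode to 0 (censored) / ",
         "1 (event) before loading", call. = FALSE)
  check_survival(tab$time, tab$status, require_events = TRUE)
  tab
}

#' Read a feature matrix
#'
#' Delimited text whose first column is the sample id and remaining
#' columns are numeric features. Duplicate ids and non-numeric cells are
#' errors.
#'
#' @param path file path.
#' @return numeric matrix with sample ids as row names.
#' @export
read_feature_matrix <- function(path) {
  tab <- .read_delim(path)
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated sample id(s) in feature matrix ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  feats <- tab[-1]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  m <- as.matrix(feats)
  if (anyNA(m))
    stop("missing values in feature matrix ", path,
         "; impute or drop explicitly before loading", call. = FALSE)
  rownames(m) <- ids
  m
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load feature matrices aligned to a survival table
#'
#' Reads one or more feature matrices and a survival table and
#' inner-joins them on sample id — never by row position — keeping the
#' samples present in every file, in sorted id order. Dropped ids are
#' reported via message.
#'
#' @param feature_paths character vector (optionally named; names become
#'   modality names) of feature-matrix files.
#' @param survival_path survival table file.
#' @return list with `x` (one matrix, or a named list of matrices when
#'   several feature files are given), `sample`, `time`, `status`,
#'   `dropped` (ids not shared by all files).
#' @export
read_survival_data <- function(feature_paths, survival_path) {
  surv <- read_survival_table(survival_path)
  mats <- lapply(feature_paths, read_feature_matrix)
  if (is.null(names(mats)))
    names(mats) <- tools::file_path_sans_ext(basename(unlist(feature_paths)))
  shared <- Reduce(intersect, c(list(surv$sample), lapply(mats, rownames)))
  if (length(shared) < 2)
    stop("fewer than two sample ids shared between survival table and ",
         "feature matrices", call. = FALSE)
  shared <- sort(shared)
  all_ids <- unique(c(surv$sample, unlist(lapply(mats, rownames))))
  dropped <- setdiff(all_ids, shared)
  if (length(dropped))
    message(length(dropped), " sample id(s) dropped (not shared by all ",
            "inputs): ", paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  surv <- surv[match(shared, surv$sample), ]
  mats <- lapply(mats, function(m) m[shared, , drop = FALSE])
  list(x = if (length(mats) == 1L) mats[[1]] else mats,
       sample = shared, time = surv$time, status = surv$status,
       dropped = dropped)
}

#' Write a feature matrix / survival table
#'
#' Tab-delimited writers matching the readers above.
#'
#' @param x matrix with sample-id row names, or a survival data.frame
#'   with columns sample/time/status.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(sample = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
write_survival_table <- function(x, path) {
  utils::write.table(x[c("sample", "time", "status")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.ARCHIVE_VERSION <- 1L

.model_checksum <- function(payload) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # version 2 serialization is stable across the R versions we support
  saveRDS(payload, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Save / load a fitted model archive
#'
#' The archive is a single RDS container holding the model's arrays and
#' configuration, a format version, and an md5 checksum of the payload;
#' loading verifies both, so a tampered or truncated archive fails
#' loudly and a future format bump gives a clear migration error. A
#' two-stage model archive embeds its first-stage models, so a loaded
#' stage-2 archive predicts standalone. Round-trips are lossless:
#' predictions from the loaded model are bit-identical.
#'
#' @param model a `coxnnet` or `coxnnet_twostage` fit.
#' @param path archive path (conventionally `.rds`).
#' @return `save_coxnnet` returns `path` invisibly; `load_coxnnet`
#'   returns the model.
#' @export
save_coxnnet <- function(model, path) {
  stopifnot(inherits(model, c("coxnnet", "coxnnet_twostage")))
  payload <- unclass(model)
  archive <- list(format = "survnnet-model",
                  version = .ARCHIVE_VERSION,
                  class = class(model),
                  checksum = .model_checksum(payload),
                  payload = payload)
  saveRDS(archive, path, version = 2)
  invisible(path)
}

#' @rdname save_coxnnet
#' @export
load_coxnnet <- function(path) {
  archive <- tryCatch(readRDS(path), error = function(e)
    stop("not a survnnet model archive: ", path, call. = FALSE))
  if (!is.list(archive) || !identical(archive$format, "survnnet-model"))
    stop("not a survnnet model archive: ", path, call. = FALSE)
  if (!identical(archive$version, .ARCHIVE_VERSION))
    stop("model archive version ", archive$version, " needs migration; ",
         "this build reads version ", .ARCHIVE_VERSION, call. = FALSE)
  if (!identical(.model_checksum(archive$payload), archive$checksum))
    stop("model archive checksum mismatch (file corrupted or tampered): ",
         path, call. = FALSE)
  structure(archive$payload, class = archive$class)
}
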