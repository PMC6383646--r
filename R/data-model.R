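#' Define the disorder panel of a superordinate category
#'
#' A disorder panel is the ordered set of D disorders whose union defines the
#' superordinate category ("any of these disorders"). The order fixes the
#' disorder index d used throughout the package.
#'
#' @param names character vector of unique disorder labels.
#' @return A character vector of class `disorder_panel`.
#' @examples
#' disorder_panel(c("panic", "ocd", "gad"))
#' @export
disorder_panel <- function(names) {
  names <- as.character(names)
  if (anyNA(names) || any(!nzchar(names)))
    stop("disorder labels must be non-missing, non-empty strings")
  if (anyDuplicated(names))
    stop("disorder labels must be unique")
  structure(names, class = "disorder_panel")
}

n_disorders <- function(panel) length(unclass(panel))

#' Assemble a meta-analytic dataset of aggregate counts and optional IPD
#'
#' @param samples data.frame with columns `sample_id`, `cluster_id`, `N`,
#'   `any_count` and one integer count column per disorder in `panel`
#'   (`NA` = disorder not measured by that sample). Samples sharing a
#'   `cluster_id` come from the same parent study and share one "true"
#'   prevalence vector in the Bayesian model. An optional logical column
#'   `ipd_available` flags samples whose IPD exist but are not attached.
#' @param panel a [disorder_panel()].
#' @param ipd named list of participant-by-disorder 0/1 matrices, one per
#'   IPD sample (names are `sample_id`s). Whole columns are `NA` when a
#'   disorder was not measured by that sample.
#' @return A validated object of class `meta_dataset`.
#' @export
meta_dataset <- function(samples, panel, ipd = list()) {
  stopifnot(inherits(panel, "disorder_panel"))
  D <- n_disorders(panel)
  req <- c("sample_id", "cluster_id", "N", "any_count", unclass(panel))
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples is missing columns: ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$cluster_id <- as.character(samples$cluster_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!("ipd_available" %in% names(samples))) samples$ipd_available <- FALSE
  samples <- samples[, c(req, "ipd_available")]

  cnt <- as.matrix(samples[, unclass(panel), drop = FALSE])
  storage.mode(cnt) <- "integer"
  if (any(samples$N < 0)) stop("sample sizes must be non-negative")
  nm <- rowSums(!is.na(cnt))
  if (any(nm < 1)) stop("every sample must measure at least one disorder")
  bad <- which(cnt > samples$N | cnt < 0, arr.ind = TRUE)
  if (nrow(bad)) stop("count exceeds N (or is negative) for sample ",
                      samples$sample_id[bad[1, 1]])
  a <- samples$any_count
  if (any(!is.na(a) & (a < 0 | a > samples$N)))
    stop("any_count outside [0, N]")
  mx <- suppressWarnings(apply(cnt, 1, max, na.rm = TRUE))
  if (any(!is.na(a) & a < mx))
    stop("any_count below the largest per-disorder count")

  if (length(ipd)) {
    if (is.null(names(ipd)) || any(!nzchar(names(ipd))))
      stop("ipd must be a named list keyed by sample_id")
    for (id in names(ipd)) {
      i <- match(id, samples$sample_id)
      if (is.na(i)) stop("IPD block '", id, "' matches no aggregate sample")
      y <- as.matrix(ipd[[id]])
      if (ncol(y) != D) stop("IPD block '", id, "' must have ", D, " columns")
      colnames(y) <- unclass(panel)
      if (nrow(y) != samples$N[i])
        stop("IPD block '", id, "' has ", nrow(y), " rows but N = ", samples$N[i])
      if (!all(y %in% c(0L, 1L, NA)))
        stop("IPD block '", id, "' contains non-binary entries")
      colna <- colSums(is.na(y))
      if (any(colna > 0 & colna < nrow(y)))
        stop("IPD block '", id, "': missingness must be column-wise")
      cs <- colSums(y)
      both <- !is.na(cs) & !is.na(cnt[i, ])
      if (any(cs[both] != cnt[i, both]))
        stop("IPD block '", id, "': column sums disagree with aggregate counts")
      meas_ipd <- colna == 0
      meas_agg <- !is.na(cnt[i, ])
      if (any(meas_agg & !meas_ipd))
        stop("IPD block '", id, "': disorder measured in aggregate but missing in IPD")
      storage.mode(y) <- "integer"
      ipd[[id]] <- y
      samples$ipd_available[i] <- TRUE
    }
  }
  structure(list(panel = panel, samples = samples, ipd = ipd),
            class = "meta_dataset")
}

#' Number of disorders measured by each sample
#'
#' @param data a [meta_dataset()].
#' @return named integer vector (one entry per sample).
#' @export
measured_disorders <- function(data) {
  stopifnot(inherits(data, "meta_dataset"))
  cnt <- data$samples[, unclass(data$panel), drop = FALSE]
  stats::setNames(rowSums(!is.na(cnt)), data$samples$sample_id)
}

#' @export
print.meta_dataset <- function(x, ...) {
  s <- x$samples
  cat("meta_dataset:", nrow(s), "samples,", length(unique(s$cluster_id)),
      "clusters,", n_disorders(x$panel), "disorders\n")
  cat("  panel:", paste(unclass(x$panel), collapse = ", "), "\n")
  cat("  total N:", sum(s$N), "| samples with any-count:",
      sum(!is.na(s$any_count)), "| IPD blocks attached:", length(x$ipd), "\n")
  invisible(x)
}

#' Read a meta-analytic dataset from CSV files
#'
#' The aggregate file has columns `sample_id, cluster_id, N, any_count` and
#' one column per disorder; empty cells mean "not measured". The optional IPD
#' file is in long form (`sample_id, participant_id`, one 0/1/empty column
#' per disorder).
#'
#' @param aggregate_path path to the aggregate CSV.
#' @param ipd_path optional path to the IPD CSV.
#' @param panel a [disorder_panel()].
#' @return A validated [meta_dataset()].
#' @export
load_dataset <- function(aggregate_path, ipd_path = NULL, panel) {
  agg <- read.csv(aggregate_path, stringsAsFactors = FALSE)
  ipd <- list()
  if (!is.null(ipd_path)) {
    long <- read.csv(ipd_path, stringsAsFactors = FALSE)
    need <- c("sample_id", "participant_id", unclass(panel))
    miss <- setdiff(need, names(long))
    if (length(miss)) stop("IPD file is missing columns: ", paste(miss, collapse = ", "))
    for (id in unique(long$sample_id)) {
      blk <- long[long$sample_id == id, , drop = FALSE]
      blk <- blk[order(blk$participant_id), , drop = FALSE]
      ipd[[id]] <- as.matrix(blk[, unclass(panel), drop = FALSE])
    }
  }
  meta_dataset(agg, panel, ipd)
}

#' Write a meta-analytic dataset to CSV files
#'
#' Emits the same dialects that [load_dataset()] reads, so that a write/read
#' round trip reproduces the dataset.
#'
#' @param data a [meta_dataset()].
#' @param aggregate_path output path for the aggregate CSV.
#' @param ipd_path optional output path for the long-form IPD CSV (required
#'   when `data` carries IPD blocks).
#' @return `data`, invisibly.
#' @export
write_dataset <- function(data, aggregate_path, ipd_path = NULL) {
  stopifnot(inherits(data, "meta_dataset"))
  out <- data$samples
  out$ipd_available <- NULL
  write.csv(out, aggregate_path, row.names = FALSE, na = "")
  if (length(data$ipd)) {
    if (is.null(ipd_path)) stop("dataset has IPD blocks; supply ipd_path")
    rows <- lapply(names(data$ipd), function(id) {
      y <- data$ipd[[id]]
      data.frame(sample_id = id, participant_id = seq_len(nrow(y)),
                 as.data.frame(y), check.names = FALSE)
    })
    write.csv(do.call(rbind, rows), ipd_path, row.names = FALSE, na = "")
  }
  invisible(data)
}
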