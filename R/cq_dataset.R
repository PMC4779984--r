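#' Hierarchically replicated Cq datasets
#'
#' A `cq_dataset` is a tibble of quantification-cycle (Cq) measurements, one
#' row per qPCR reaction, carrying the full nested coordinates of the RT-qPCR
#' workflow: biological subject, tissue, gene (assay), RNA-extraction
#' replicate, reverse-transcription replicate within the extraction, and qPCR
#' replicate within the RT reaction. Missing Cq values (failed or discarded
#' reactions) are kept as `NA` rows so that design bookkeeping stays explicit.
#'
#' Replicate indices are nominal labels: all estimation downstream is
#' invariant to renumbering them. Cq values are on the cycle scale; no
#' amplification-efficiency correction is applied at ingest.
#'
#' @param records A data.frame with columns `subject`, `tissue`, `gene`
#'   (character), `rna_rep`, `rt_rep`, `qpcr_rep` (positive integers) and
#'   `cq` (finite positive numeric, or `NA` for a missing reaction).
#' @param provenance Free-text note recording where the data came from.
#'
#' @return A tibble with class `cq_dataset` and a `provenance` attribute.
#' @export
#' @examples
#' ds <- cq_dataset(data.frame(
#'   subject = "P1", tissue = "leaves", gene = "VRN",
#'   rna_rep = 1L, rt_rep = 1L, qpcr_rep = 1:3,
#'   cq = c(25.1, 25.3, 24.9)
#' ))
#' summarize_counts(ds)
cq_dataset <- function(records, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cq_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(records), cq_columns())
  if (length(extra) > 0) {
    stop("unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, cq_columns()]
  for (col in c("subject", "tissue", "gene")) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in c("rna_rep", "rt_rep", "qpcr_rep")) {
    idx <- records[[col]]
    if (!is.numeric(idx) || anyNA(idx) || any(idx != as.integer(idx)) ||
        any(idx < 1)) {
      stop("column '", col, "' must contain integer indices >= 1",
           call. = FALSE)
    }
    records[[col]] <- as.integer(idx)
  }
  cq <- records[["cq"]]
  if (!is.numeric(cq)) stop("column 'cq' must be numeric", call. = FALSE)
  bad <- !is.na(cq) & (!is.finite(cq) | cq <= 0)
  if (any(bad)) {
    stop("cq values must be finite and > 0 (or missing); offending row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  records[["cq"]] <- as.numeric(cq)

  key <- do.call(paste, c(records[coordinate_columns()], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), coordinate_columns(), drop = FALSE]
    stop("duplicate coordinate tuple(s), e.g. ",
         paste(unlist(dup[1, ]), collapse = "/"), call. = FALSE)
  }

  if (nrow(records) > 0) {
    stratum <- interaction(records$subject, records$tissue, records$gene,
                           drop = TRUE)
    n_obs <- tapply(!is.na(records$cq), stratum, sum)
    if (any(n_obs == 0)) {
      stop("stratum with no non-missing Cq value: ",
           names(n_obs)[which(n_obs == 0)[1]], call. = FALSE)
    }
  }

  out <- tibble::as_tibble(records)
  class(out) <- c("cq_dataset", class(out))
  attr(out, "provenance") <- provenance
  out
}

cq_columns <- function() {
  c("subject", "tissue", "gene", "rna_rep", "rt_rep", "qpcr_rep", "cq")
}

coordinate_columns <- function() {
  c("subject", "tissue", "gene", "rna_rep", "rt_rep", "qpcr_rep")
}

#' Read a long-format Cq CSV
#'
#' Reads one Cq record per row from a UTF-8 CSV whose header is exactly
#' `subject,tissue,gene,rna_rep,rt_rep,qpcr_rep,cq`. An empty `cq` field
#' marks a missing reaction; absent rows are tolerated and treated the same
#' way by the counting helpers.
#'
#' @param path Path to the CSV file.
#' @return A validated [cq_dataset()].
#' @export
read_cq_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (!identical(header, cq_columns())) {
    missing_cols <- setdiff(cq_columns(), header)
    extra <- setdiff(header, cq_columns())
    msg <- "CSV header must be exactly 'subject,tissue,gene,rna_rep,rt_rep,qpcr_rep,cq'"
    if (length(missing_cols) > 0) {
      msg <- paste0(msg, "; missing: ", paste(missing_cols, collapse = ", "))
    }
    if (length(extra) > 0) {
      msg <- paste0(msg, "; unexpected: ", paste(extra, collapse = ", "))
    }
    stop(msg, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = c(
    subject = "character", tissue = "character", gene = "character",
    rna_rep = "integer", rt_rep = "integer", qpcr_rep = "integer",
    cq = "character"
  ), na.strings = "")
  cq_chr <- trimws(raw$cq)
  cq <- suppressWarnings(as.numeric(cq_chr))
  non_numeric <- !is.na(cq_chr) & cq_chr != "" & is.na(cq)
  if (any(non_numeric)) {
    stop("non-numeric cq value(s) at data row(s): ",
         paste(utils::head(which(non_numeric), 5), collapse = ", "),
         call. = FALSE)
  }
  raw$cq <- cq
  cq_dataset(raw, provenance = paste0("read from ", path))
}

#' Write a Cq dataset to long-format CSV
#'
#' Inverse of [read_cq_csv()]: missing Cq values are written as empty fields,
#' and numeric Cq values are written with enough digits that a read/write
#' round trip reproduces the dataset exactly.
#'
#' @param ds A [cq_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cq_csv <- function(ds, path) {
  stopifnot(inherits(ds, "cq_dataset"))
  out <- as.data.frame(ds)
  out$cq <- ifelse(is.na(out$cq), "", sprintf("%.17g", out$cq))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-stratum record counts
#'
#' Counts observed (non-missing) and missing-marked records for every
#' (subject, tissue, gene) stratum. When the nominal design dimensions are
#' declared, the missing count is reported against the expected
#' `n_sampling * n_rt * n_qpcr` records so that reactions absent from the
#' file (rather than marked with an empty Cq) are also counted as missing.
#'
#' @param ds A [cq_dataset()].
#' @param dims Optional integer vector `c(n_sampling, n_rt, n_qpcr)` giving
#'   the designed replicate numbers per stratum.
#' @return A tibble with one row per stratum: `subject`, `tissue`, `gene`,
#'   `n_observed`, `n_missing_marked`, and (when `dims` is given)
#'   `n_expected` and `n_missing`.
#' @export
summarize_counts <- function(ds, dims = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (nrow(ds) == 0) {
    out <- tibble::tibble(subject = character(), tissue = character(),
                          gene = character(), n_observed = integer(),
                          n_missing_marked = integer())
    if (!is.null(dims)) {
      out$n_expected <- integer()
      out$n_missing <- integer()
    }
    return(out)
  }
  df <- as.data.frame(ds)
  keys <- unique(df[c("subject", "tissue", "gene")])
  keys <- keys[order(keys$subject, keys$tissue, keys$gene), , drop = FALSE]
  stratum_of <- function(d) paste(d$subject, d$tissue, d$gene, sep = "\r")
  sk <- stratum_of(df)
  kk <- stratum_of(keys)
  n_obs <- as.integer(tapply(!is.na(df$cq), sk, sum)[kk])
  n_marked <- as.integer(tapply(is.na(df$cq), sk, sum)[kk])
  out <- tibble::tibble(subject = keys$subject, tissue = keys$tissue,
                        gene = keys$gene, n_observed = n_obs,
                        n_missing_marked = n_marked)
  if (!is.null(dims)) {
    stopifnot(length(dims) == 3, all(dims >= 1))
    n_expected <- as.integer(prod(dims))
    out$n_expected <- n_expected
    out$n_missing <- n_expected - out$n_observed
  }
  out
}

#' Check strata for variance-component estimability
#'
#' Walks every (subject, tissue, gene) stratum and reports, without failing,
#' which variance components cannot be estimated from it: fewer than two RNA
#' extractions (no sampling-level degrees of freedom), no extraction with two
#' or more RT reactions (no RT-level df), or no RT with two or more qPCR
#' replicates (no qPCR-level df). Only non-missing records count.
#'
#' @param ds A [cq_dataset()].
#' @return A tibble of findings with columns `subject`, `tissue`, `gene`,
#'   `level`, `message`; zero rows when every stratum supports full
#'   estimation.
#' @export
validate_hierarchy <- function(ds) {
  stopifnot(inherits(ds, "cq_dataset"))
  empty <- tibble::tibble(subject = character(), tissue = character(),
                          gene = character(), level = character(),
                          message = character())
  if (nrow(ds) == 0) return(empty)
  df <- as.data.frame(ds)
  df <- df[!is.na(df$cq), , drop = FALSE]
  findings <- list()
  for (piece in split(df, paste(df$subject, df$tissue, df$gene, sep = "\r"))) {
    key <- piece[1, c("subject", "tissue", "gene")]
    d <- nested_df_counts(piece)
    add <- function(level, message) {
      findings[[length(findings) + 1]] <<- tibble::tibble(
        subject = key$subject, tissue = key$tissue, gene = key$gene,
        level = level, message = message)
    }
    if (d$df_sampling < 1) {
      add("sampling", "fewer than 2 RNA extractions: sampling-level variance not estimable")
    }
    if (d$df_rt < 1) {
      add("rt", "no extraction has 2 or more RT reactions: RT-level variance not estimable")
    }
    if (d$df_qpcr < 1) {
      add("qpcr", "no RT reaction has 2 or more qPCR replicates: qPCR-level variance not estimable")
    }
  }
  if (length(findings) == 0) return(empty)
  do.call(rbind, findings)
}

# Degrees of freedom of the fully nested layout realized by the (complete
# case) records of one stratum: a extractions, b_i RTs within extraction i,
# N observations. df_sampling = a - 1, df_rt = sum(b_i - 1),
# df_qpcr = N - sum(b_i).
nested_df_counts <- function(piece) {
  a <- length(unique(piece$rna_rep))
  bi <- tapply(piece$rt_rep, piece$rna_rep, function(x) length(unique(x)))
  list(
    n = nrow(piece),
    a = a,
    df_sampling = a - 1L,
    df_rt = sum(bi - 1L),
    df_qpcr = nrow(piece) - sum(bi)
  )
}

#' @export
print.cq_dataset <- function(x, ...) {
  n_miss <- sum(is.na(x$cq))
  cat(sprintf("<cq_dataset> %d records (%d missing Cq)\n", nrow(x), n_miss))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("provenance:", prov, "\n")
  NextMethod()
}
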