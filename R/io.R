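# Readers and writers: canonical TSV count tables, fitness tables, and the
# CSV dialect of public deep-mutational-scanning deposits (normalized
# fitness metrics + read counts + raw log2 enrichment scores).

count_columns <- c("variant", "position", "wt_aa", "mut_aa", "codon",
                   "replicate", "pre_count", "post_count")

#' Write / read a variant count table (canonical TSV)
#'
#' Columns: `variant`, `position`, `wt_aa`, `mut_aa`, `codon`, `replicate`,
#' `pre_count`, `post_count`.  The reader validates rather than coerces:
#' missing required columns, non-integer or negative counts, NA counts and
#' duplicated members are rejected with row numbers.
#'
#' @param counts a count table data.frame.
#' @param path file path.
#' @param dialect `"tsv"` (canonical) or `"csv"`.
#' @return `read_count_table`: a `count_table` data.frame.
#' @export
write_count_table <- function(counts, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  write.table(as.data.frame(counts)[, intersect(count_columns,
                                                names(counts))],
              path, sep = if (dialect == "tsv") "\t" else ",",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (dialect == "tsv") {
    read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  } else {
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
  req <- c("variant", "pre_count", "post_count")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  for (col in c("pre_count", "post_count")) {
    v <- suppressWarnings(as.numeric(as.character(df[[col]])))
    bad <- which(is.na(v) | !is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop("parse error: invalid ", col, " at row(s) ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    df[[col]] <- as.integer(v)
  }
  if (is.null(df$codon)) df$codon <- 1L
  if (is.null(df$replicate)) df$replicate <- 1L
  key <- paste(df$variant, df$codon, df$replicate)
  if (anyDuplicated(key)) {
    stop("parse error: duplicated member(s) at row(s) ",
         paste(utils::head(which(duplicated(key)), 10L), collapse = ", "))
  }
  structure(df, class = c("count_table", "data.frame"))
}

#' Write a fitness table (TSV) with its summary attributes
#'
#' Writes the per-member table and, alongside it, a JSON summary
#' (`<path>.summary.json`) carrying the selection-level quantities:
#' wild-type enrichment ratio, detection limit, doublings, totals, coverage.
#'
#' @param fit a `fitness_table`.
#' @param path output TSV path.
#' @export
write_fitness_table <- function(fit, path) {
  write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  summ <- list(label = attr(fit, "label"),
               epsilon_wt = attr(fit, "epsilon_wt"),
               epsilon_lb = attr(fit, "epsilon_lb"),
               zeta_lb = attr(fit, "zeta_lb"),
               g_p = attr(fit, "g_p"),
               pre_total = attr(fit, "pre_total"),
               post_total = attr(fit, "post_total"),
               coverage = attr(fit, "coverage"))
  jsonlite::write_json(summ[!vapply(summ, is.null, TRUE)],
                       paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a public-deposit fitness CSV (configurable column mapping)
#'
#' Reads the CSV dialect used by public deep-mutational-scanning deposits in
#' which each row carries a variant's normalized fitness metric together
#' with its read counts and raw log2 enrichment score.  Column names vary
#' between deposits, so the mapping is configuration, not convention.
#'
#' @param path CSV file.
#' @param mapping named list mapping canonical fields (`variant`, `zeta`,
#'   and optionally `epsilon`, `pre_count`, `post_count`) to the file's
#'   column names.
#' @return data.frame of class `fitness_table` with the canonical columns
#'   present in the mapping plus parsed `position`, `wt_aa`, `mut_aa`,
#'   `type`.
#' @export
read_fitness_csv <- function(path,
                             mapping = list(variant = "variant",
                                            zeta = "fitness",
                                            epsilon = "log2_enrichment",
                                            pre_count = "pre_count",
                                            post_count = "post_count")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant", "zeta")
  for (f in need) {
    if (is.null(mapping[[f]]) || !mapping[[f]] %in% names(df)) {
      stop("schema error: no column mapped for '", f, "'")
    }
  }
  out <- parse_variant(df[[mapping$variant]])
  out$zeta <- as.numeric(df[[mapping$zeta]])
  for (f in c("epsilon", "pre_count", "post_count")) {
    if (!is.null(mapping[[f]]) && mapping[[f]] %in% names(df)) {
      out[[f]] <- as.numeric(df[[mapping[[f]]]])
    }
  }
  if (anyNA(out$zeta)) {
    stop("parse error: non-numeric fitness at row(s) ",
         paste(utils::head(which(is.na(out$zeta)), 10L), collapse = ", "))
  }
  structure(out, class = c("fitness_table", "data.frame"))
}

#' Write ground truth of a simulated selection (TSV)
#'
#' @param truth a [sample_true_dfe()] table.
#' @param path output TSV path.
#' @export
write_truth_table <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
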