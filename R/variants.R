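# Variant identities and site-saturation library enumeration.

#' The twenty proteinogenic amino acids (one-letter codes)
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Format a variant identity string
#'
#' Variants are written in the conventional `"S9A"` style: wild-type residue,
#' 1-based position, mutant residue, with `"*"` for a stop codon.  The
#' wild-type member of a library is written `"WT"`.
#'
#' @param wt_aa,mut_aa one-letter residue codes (`"*"` allowed for `mut_aa`).
#' @param position 1-based residue position.
#' @return character vector of identity strings.
#' @seealso [parse_variant()]
#' @export
format_variant <- function(wt_aa, position, mut_aa) {
  paste0(wt_aa, position, mut_aa)
}

#' Parse variant identity strings
#'
#' Strict parser for `"S9A"`-style identities (wild-type residue, 1-based
#' position, mutant residue; `"*"` denotes a stop codon).  `"WT"` is accepted
#' and returns an `NA` position.
#'
#' @param x character vector of identity strings.
#' @return data.frame with columns `variant`, `position`, `wt_aa`, `mut_aa`,
#'   and `type` (`"wt"`, `"missense"` or `"nonsense"`).
#' @examples
#' parse_variant(c("S9A", "M202*", "WT"))
#' @export
parse_variant <- function(x) {
  out <- data.frame(variant = x, position = NA_integer_,
                    wt_aa = NA_character_, mut_aa = NA_character_,
                    type = NA_character_, stringsAsFactors = FALSE)
  is_wt <- x == "WT"
  aa <- paste(AA_ALPHABET, collapse = "")
  pat <- sprintf("^([%s])([0-9]+)([%s*])$", aa, aa)
  m <- regmatches(x, regexec(pat, x))
  bad <- !is_wt & lengths(m) != 4L
  if (any(bad)) {
    stop("malformed variant identities: ", paste(x[bad], collapse = ", "))
  }
  hit <- !is_wt
  out$wt_aa[hit] <- vapply(m[hit], `[`, "", 2L)
  out$position[hit] <- as.integer(vapply(m[hit], `[`, "", 3L))
  out$mut_aa[hit] <- vapply(m[hit], `[`, "", 4L)
  out$type[is_wt] <- "wt"
  out$type[hit] <- ifelse(out$mut_aa[hit] == "*", "nonsense", "missense")
  ok <- is_wt | (out$wt_aa != out$mut_aa)
  if (any(!ok)) {
    stop("synonymous-looking identities (wt == mut): ",
         paste(x[!ok], collapse = ", "))
  }
  out
}

#' Specification of a site-saturation library
#'
#' Describes the variant universe and the statistical structure of the
#' pre-selection population: every position carries the 19 amino-acid
#' substitutions (plus, optionally, a stop), possibly encoded by several
#' synonymous codons, and per-member pre-selection abundances are log-normal.
#'
#' @param protein_length number of residues (>= 1).
#' @param codons_per_variant synonymous codon slots per protein-level variant
#'   (>= 1).
#' @param include_stop include the nonsense (stop) substitution at every
#'   position.
#' @param pre_abundance_logmean,pre_abundance_logsd meanlog / sdlog of the
#'   log-normal pre-selection abundance per library member (sdlog >= 0).
#' @param sequencing_depth_pre,sequencing_depth_post total read counts drawn
#'   for the pre- and post-selection populations.
#' @return an object of class `library_spec`.
#' @examples
#' library_spec(protein_length = 341)
#' @export
library_spec <- function(protein_length,
                         codons_per_variant = 1L,
                         include_stop = TRUE,
                         pre_abundance_logmean = log(100),
                         pre_abundance_logsd = 1,
                         sequencing_depth_pre = 1e6,
                         sequencing_depth_post = 1e6) {
  if (!is.numeric(protein_length) || length(protein_length) != 1L ||
      is.na(protein_length) || protein_length < 1) {
    stop("invalid library spec: protein_length must be >= 1")
  }
  if (codons_per_variant < 1) {
    stop("invalid library spec: codons_per_variant must be >= 1")
  }
  if (pre_abundance_logsd < 0) {
    stop("invalid library spec: pre_abundance_logsd must be >= 0")
  }
  structure(list(protein_length = as.integer(protein_length),
                 codons_per_variant = as.integer(codons_per_variant),
                 include_stop = isTRUE(include_stop),
                 pre_abundance_logmean = pre_abundance_logmean,
                 pre_abundance_logsd = pre_abundance_logsd,
                 sequencing_depth_pre = sequencing_depth_pre,
                 sequencing_depth_post = sequencing_depth_post),
            class = "library_spec")
}

#' Enumerate a site-saturation variant universe with pre-selection abundances
#'
#' Generates every single substitution over the protein (19 amino-acid
#' exchanges per position, plus a stop when `include_stop` is set), one row
#' per synonymous codon slot, together with the wild-type member, and assigns
#' each member a log-normal pre-selection abundance.  For a 341-residue
#' protein with stops this yields the familiar 341 x 20 = 6,820 single
#' nonsynonymous variants.
#'
#' @param spec a [library_spec()].
#' @param wt_sequence optional wild-type sequence (single string or character
#'   vector of one-letter codes, length `protein_length`); a random sequence
#'   is drawn when omitted.
#' @param seed optional integer seed for the abundance draw (and the random
#'   sequence, when used).
#' @return data.frame of class `variant_library` with columns `variant`,
#'   `position`, `wt_aa`, `mut_aa`, `codon` (synonymous slot index), `type`
#'   and `abundance`; the wild-type sequence and spec are kept as attributes.
#' @examples
#' lib <- make_library(library_spec(protein_length = 3), seed = 1)
#' nrow(lib)  # 3 x 20 nonsynonymous members + WT
#' @export
make_library <- function(spec, wt_sequence = NULL, seed = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  if (!is.null(seed)) set.seed(seed)
  L <- spec$protein_length
  if (is.null(wt_sequence)) {
    wt_sequence <- sample(AA_ALPHABET, L, replace = TRUE)
  } else {
    if (length(wt_sequence) == 1L && nchar(wt_sequence) > 1L) {
      wt_sequence <- strsplit(wt_sequence, "")[[1L]]
    }
    if (length(wt_sequence) != L) {
      stop("wt_sequence length (", length(wt_sequence),
           ") does not match protein_length (", L, ")")
    }
    if (!all(wt_sequence %in% AA_ALPHABET)) {
      stop("wt_sequence contains non-standard residues")
    }
  }
  subs_per_pos <- 19L + as.integer(spec$include_stop)
  position <- rep(seq_len(L), each = subs_per_pos)
  wt_aa <- wt_sequence[position]
  mut_aa <- unlist(lapply(seq_len(L), function(p) {
    m <- setdiff(AA_ALPHABET, wt_sequence[p])
    if (spec$include_stop) m <- c(m, "*")
    m
  }), use.names = FALSE)
  # one row per synonymous codon slot
  k <- spec$codons_per_variant
  df <- data.frame(
    variant = rep(format_variant(wt_aa, position, mut_aa), times = k),
    position = rep(position, times = k),
    wt_aa = rep(wt_aa, times = k),
    mut_aa = rep(mut_aa, times = k),
    codon = rep(seq_len(k), each = L * subs_per_pos),
    stringsAsFactors = FALSE
  )
  df$type <- ifelse(df$mut_aa == "*", "nonsense", "missense")
  wt_row <- data.frame(variant = "WT", position = NA_integer_,
                       wt_aa = NA_character_, mut_aa = NA_character_,
                       codon = 1L, type = "wt", stringsAsFactors = FALSE)
  df$abundance <- rlnorm(nrow(df), spec$pre_abundance_logmean,
                         spec$pre_abundance_logsd)
  wt_row$abundance <- rlnorm(1L, spec$pre_abundance_logmean,
                             spec$pre_abundance_logsd)
  out <- rbind(wt_row, df)
  rownames(out) <- NULL
  structure(out, wt_sequence = wt_sequence, spec = spec,
            class = c("variant_library", "data.frame"))
}
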