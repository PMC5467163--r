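# Normalized fitness metrics from pre/post selection read counts.
#
# eps_i = log2(f_post,i / f_pre,i)         (enrichment ratio, log2 units)
# zeta_i = (eps_i - eps_WT) / g_p          (wild-type-normalized fitness)
#
# The detection limit is anchored to a floor of post-selection reads: a
# variant whose pre-selection representation equals the half-median cannot be
# quantified below zeta_LB, only called "deleterious" categorically.

#' Enrichment ratio of a library member
#'
#' `eps = log2((post/post_total) / (pre/pre_total))`.  Invariant to
#' proportional scaling of both totals.  A variant unobserved pre-selection
#' is unquantifiable and returns `NA` (it should be dropped, not imputed).
#' A zero post-selection count is replaced by `zero_post_floor` reads
#' (default 0.5) so a finite — categorical — value can be carried.
#'
#' @param pre_count,post_count reads for the member.
#' @param pre_total,post_total total reads in each population.
#' @param zero_post_floor pseudo-count substituted for a zero post count.
#' @return enrichment ratio(s) in log2 units.
#' @examples
#' enrichment_ratio(100, 400, 1e6, 2e6)  # 1
#' @export
enrichment_ratio <- function(pre_count, post_count, pre_total, post_total,
                             zero_post_floor = 0.5) {
  if (pre_total <= 0 || post_total <= 0) stop("population totals must be > 0")
  post <- ifelse(post_count == 0, zero_post_floor, post_count)
  eps <- log2((post / post_total) / (pre_count / pre_total))
  eps[pre_count == 0] <- NA_real_
  eps
}

#' Wild-type-normalized fitness metric
#'
#' `zeta = (eps_i - eps_wt) / g_p`.  Zero for the wild type by construction;
#' `zeta = 0.15` corresponds to roughly a 10% growth-rate advantage at the
#' study's calibration.
#'
#' @param epsilon enrichment ratio(s) of the variant(s).
#' @param epsilon_wt wild-type enrichment ratio.
#' @param g_p population doublings (> 0).
#' @return fitness metric(s).
#' @export
fitness_metric <- function(epsilon, epsilon_wt, g_p) {
  if (g_p <= 0) stop("g_p must be > 0")
  (epsilon - epsilon_wt) / g_p
}

#' Detection-limit (lower-bound) fitness metric
#'
#' The half-median of pre-selection per-variant read counts, normalized by
#' the ratio of post- to pre-selection read counts, gives the post-scale
#' representation `f_LB` of a typical half-covered variant; the lower-bound
#' enrichment ratio is then `eps_LB = log2(floor_reads / f_LB)` (anchored at
#' `floor_reads` post-selection reads, default 10), and
#' `zeta_LB = (eps_LB - eps_wt)/g_p`.  Variants with `zeta < zeta_LB` can be
#' called "deleterious" only categorically.
#'
#' @param pre_half_median half the median pre-selection per-variant reads.
#' @param post_to_pre_ratio ratio of post- to pre-selection total reads.
#' @param floor_reads post-selection read floor (default 10; > 0).
#' @param g_p population doublings.
#' @param epsilon_wt wild-type enrichment ratio.
#' @return list with `f_lb`, `epsilon_lb`, `zeta_lb`.
#' @examples
#' # a selection with half-median 49, post/pre ratio 1.86 and eps_wt 3.21
#' lower_bound_fitness(49, 1.86, 10, 8, 3.21)$zeta_lb  # ~ -0.80
#' @export
lower_bound_fitness <- function(pre_half_median, post_to_pre_ratio,
                                floor_reads = 10, g_p = 8, epsilon_wt) {
  if (floor_reads <= 0) stop("invalid spec: floor_reads must be > 0")
  if (pre_half_median <= 0 || post_to_pre_ratio <= 0 || g_p <= 0) {
    stop("invalid spec: pre_half_median, post_to_pre_ratio and g_p must be > 0")
  }
  f_lb <- pre_half_median * post_to_pre_ratio
  epsilon_lb <- log2(floor_reads / f_lb)
  list(f_lb = f_lb, epsilon_lb = epsilon_lb,
       zeta_lb = (epsilon_lb - epsilon_wt) / g_p)
}

#' Combine replicate count tables by summing reads
#'
#' Counting (Poisson) noise dominates deep-sequencing fitness measurements,
#' so replicates are pooled by summing reads per member per population and
#' the analysis repeated on the pooled table.
#'
#' @param tables a `count_table` with a `replicate` column, or a list of
#'   count tables over the identical variant universe.
#' @return a single-replicate `count_table` with summed counts.
#' @export
combine_replicates <- function(tables) {
  if (is.data.frame(tables)) {
    tabs <- split(tables, tables$replicate)
  } else {
    tabs <- tables
  }
  if (length(tabs) == 1L) {
    out <- tabs[[1L]]
    out$replicate <- 1L
    return(out)
  }
  key <- function(t) paste(t$variant, t$codon)
  k1 <- sort(key(tabs[[1L]]))
  for (i in seq_along(tabs)[-1L]) {
    ki <- sort(key(tabs[[i]]))
    if (!identical(k1, ki)) {
      off <- c(setdiff(k1, ki), setdiff(ki, k1))
      stop("replicate universes differ; offending members: ",
           paste(utils::head(off, 10L), collapse = ", "))
    }
  }
  out <- tabs[[1L]]
  ord <- key(out)
  for (i in seq_along(tabs)[-1L]) {
    t <- tabs[[i]]
    m <- match(ord, key(t))
    out$pre_count <- out$pre_count + t$pre_count[m]
    out$post_count <- out$post_count + t$post_count[m]
  }
  out$replicate <- 1L
  for (a in c("g_wt", "g_p", "seed")) {
    if (!is.null(attr(tabs[[1L]], a))) attr(out, a) <- attr(tabs[[1L]], a)
  }
  class(out) <- c("count_table", "data.frame")
  out
}

#' Theoretical (counting-noise) standard deviation of a fitness metric
#'
#' Poisson counting error propagated through the enrichment-ratio and
#' normalization equations:
#' `var(eps) = (1/pre + 1/post) / ln(2)^2` and
#' `var(zeta) = (var(eps_i) + var(eps_wt)) / g_p^2`.
#' Any zero count makes the error infinite (the variant is at the detection
#' limit).
#'
#' @param pre_count,post_count variant reads.
#' @param wt_pre,wt_post wild-type reads.
#' @param g_p population doublings.
#' @return standard deviation(s) of zeta.
#' @export
theoretical_error <- function(pre_count, post_count, wt_pre, wt_post, g_p) {
  if (g_p <= 0) stop("g_p must be > 0")
  v_eps <- function(a, b) {
    v <- (1 / a + 1 / b) / log(2)^2
    v[a == 0 | b == 0] <- Inf
    v
  }
  sqrt((v_eps(pre_count, post_count) + v_eps(wt_pre, wt_post)) / g_p^2)
}

#' Classify a fitness metric as beneficial
#'
#' Beneficial means at least ~10% growth-rate increase over wild type, i.e.
#' `zeta > 0.15` (strict).
#'
#' @param zeta fitness metric(s).
#' @param threshold beneficial threshold (default 0.15).
#' @return logical vector.
#' @export
classify_beneficial <- function(zeta, threshold = 0.15) {
  zeta > threshold
}

#' Compute a fitness table from a count table
#'
#' The central normalization step: per-member enrichment ratios, wild-type
#' normalized fitness metrics, theoretical counting error, the selection's
#' detection limit and below-bound flags.  Variants unobserved pre-selection
#' are dropped (coverage is reported); zero post-selection counts receive a
#' configurable pseudo-count and are always flagged below the bound.
#'
#' @param counts a single-replicate `count_table` (see
#'   [combine_replicates()] to pool replicates first); must contain the
#'   wild-type member (`variant == "WT"`).
#' @param g_p population doublings of this selection (default 8).
#' @param floor_reads post-selection read floor anchoring the detection limit.
#' @param zero_post_floor pseudo-count for zero post-selection reads.
#' @param label optional selection (substrate) label carried in attributes.
#' @return data.frame of class `fitness_table` with columns `variant`,
#'   `position`, `wt_aa`, `mut_aa`, `codon`, `type`, `pre_count`,
#'   `post_count`, `epsilon`, `zeta`, `theoretical_sd`,
#'   `below_lower_bound`, `beneficial`.  Attributes: `epsilon_wt`,
#'   `epsilon_lb`, `zeta_lb`, `g_p`, `pre_total`, `post_total`,
#'   `pre_half_median`, `post_pre_ratio`, `coverage`, `label`.
#' @export
compute_fitness <- function(counts, g_p = 8, floor_reads = 10,
                            zero_post_floor = 0.5, label = NULL) {
  req <- c("variant", "pre_count", "post_count")
  if (!all(req %in% names(counts))) {
    stop("count table lacks required columns: ",
         paste(setdiff(req, names(counts)), collapse = ", "))
  }
  if (!is.null(counts$replicate) && length(unique(counts$replicate)) > 1L) {
    stop("multiple replicates present; pool them with combine_replicates()")
  }
  wt_i <- which(counts$variant == "WT")
  if (length(wt_i) != 1L) {
    stop("count table must contain exactly one wild-type member ('WT')")
  }
  pre_total <- sum(counts$pre_count)
  post_total <- sum(counts$post_count)
  if (counts$pre_count[wt_i] == 0 || counts$post_count[wt_i] == 0) {
    stop("wild-type member has a zero count; cannot normalize")
  }
  n_in <- nrow(counts)
  observed <- counts$pre_count > 0
  coverage <- sum(observed & counts$variant != "WT") / (n_in - 1L)
  tab <- counts[observed, , drop = FALSE]
  eps_wt <- enrichment_ratio(counts$pre_count[wt_i], counts$post_count[wt_i],
                             pre_total, post_total)
  eps <- enrichment_ratio(tab$pre_count, tab$post_count,
                          pre_total, post_total, zero_post_floor)
  zeta <- fitness_metric(eps, eps_wt, g_p)
  zeta[tab$variant == "WT"] <- 0  # exact by construction
  sd_z <- theoretical_error(tab$pre_count, tab$post_count,
                            counts$pre_count[wt_i], counts$post_count[wt_i],
                            g_p)
  half_med <- 0.5 * median(tab$pre_count)
  ratio <- post_total / pre_total
  lb <- lower_bound_fitness(half_med, ratio, floor_reads, g_p, eps_wt)
  below <- zeta < lb$zeta_lb | tab$post_count == 0
  below[tab$variant == "WT"] <- FALSE
  out <- data.frame(tab[, intersect(c("variant", "position", "wt_aa",
                                      "mut_aa", "codon", "type"),
                                    names(tab)), drop = FALSE],
                    pre_count = tab$pre_count, post_count = tab$post_count,
                    epsilon = eps, zeta = zeta, theoretical_sd = sd_z,
                    below_lower_bound = below,
                    beneficial = classify_beneficial(zeta),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, epsilon_wt = eps_wt, epsilon_lb = lb$epsilon_lb,
            zeta_lb = lb$zeta_lb, g_p = g_p, pre_total = pre_total,
            post_total = post_total, pre_half_median = half_med,
            post_pre_ratio = ratio, coverage = coverage, label = label,
            class = c("fitness_table", "data.frame"))
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("fitness_table: ", nrow(x), " members",
      if (!is.null(attr(x, "label"))) paste0(" (", attr(x, "label"), ")"),
      "\n  eps_wt = ", format(attr(x, "epsilon_wt"), digits = 4),
      ", zeta_lb = ", format(attr(x, "zeta_lb"), digits = 4),
      ", g_p = ", attr(x, "g_p"),
      ", coverage = ", format(100 * attr(x, "coverage"), digits = 4), "%\n",
      sep = "")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Pearson correlation of fitness metrics between replicates
#'
#' Correlates per-member fitness metrics of two replicate selections, with
#' the option of excluding members below either replicate's detection limit
#' (point estimates below the bound are categorical, and including them
#' deflates the correlation).  P value from the two-tailed t transform with
#' n - 2 degrees of freedom.
#'
#' @param fit_a,fit_b `fitness_table`s (or data.frames with `variant` and
#'   `zeta`) from replicate selections.
#' @param zeta_lb length-2 (or 1, recycled) lower bounds; defaults to each
#'   table's own `zeta_lb` attribute.
#' @param exclude_below drop members below either bound before correlating.
#' @return list with `r`, `p`, `n`.
#' @export
replicate_correlation <- function(fit_a, fit_b, zeta_lb = NULL,
                                  exclude_below = TRUE) {
  if (is.null(zeta_lb)) {
    zeta_lb <- c(attr(fit_a, "zeta_lb") %||% -Inf,
                 attr(fit_b, "zeta_lb") %||% -Inf)
  }
  zeta_lb <- rep_len(zeta_lb, 2L)
  ka <- paste(fit_a$variant, fit_a$codon %||% 1L)
  kb <- paste(fit_b$variant, fit_b$codon %||% 1L)
  m <- match(ka, kb)
  keep <- !is.na(m) & fit_a$variant != "WT"
  za <- fit_a$zeta[keep]
  zb <- fit_b$zeta[m[keep]]
  if (exclude_below) {
    ok <- za >= zeta_lb[1L] & zb >= zeta_lb[2L]
    za <- za[ok]; zb <- zb[ok]
  }
  if (length(za) < 3L) {
    stop("insufficient data: fewer than 3 shared members after filtering")
  }
  ct <- cor.test(za, zb, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(za))
}

#' Read-count-weighted mean of synonymous-codon fitness metrics
#'
#' Synonymous codon members of one protein variant are summarized by a mean
#' weighted by read counts (depth of coverage) and the corresponding weighted
#' standard deviation.
#'
#' @param zeta fitness metrics of the synonymous members (>= 1 value).
#' @param weights read counts per member (same length; not all zero).
#' @return list with `mean`, `sd` (0 for a single member), `n`.
#' @examples
#' synonymous_weighted_mean(c(0.1, 0.3), c(1, 3))  # mean 0.25
#' @export
synonymous_weighted_mean <- function(zeta, weights) {
  if (length(zeta) < 1L) stop("at least one record is required")
  if (length(weights) != length(zeta)) stop("weights length mismatch")
  if (all(weights == 0)) stop("invalid weights: all zero")
  w <- weights / sum(weights)
  m <- sum(w * zeta)
  s <- if (length(zeta) == 1L) 0 else sqrt(sum(w * (zeta - m)^2))
  list(mean = m, sd = s, n = length(zeta))
}

#' Aggregate codon-level fitness records to protein level
#'
#' Applies [synonymous_weighted_mean()] per protein variant, weighting each
#' codon member by its read depth.
#'
#' @param fit a `fitness_table` with codon-level rows.
#' @param weight_by which counts serve as weights: pre+post (`"both"`,
#'   default), `"pre"` or `"post"`.
#' @return data.frame with one row per protein variant: `variant`,
#'   `position`, `wt_aa`, `mut_aa`, `type`, `zeta` (weighted mean),
#'   `zeta_sd` (weighted s.d.), `n_codons`, `below_lower_bound` (all codon
#'   members below), `beneficial`.
#' @export
aggregate_synonymous <- function(fit, weight_by = c("both", "pre", "post")) {
  weight_by <- match.arg(weight_by)
  w <- switch(weight_by,
              both = fit$pre_count + fit$post_count,
              pre = fit$pre_count,
              post = fit$post_count)
  parts <- split(seq_len(nrow(fit)), fit$variant)
  rows <- lapply(parts, function(i) {
    sm <- synonymous_weighted_mean(fit$zeta[i], w[i])
    data.frame(variant = fit$variant[i[1L]], position = fit$position[i[1L]],
               wt_aa = fit$wt_aa[i[1L]], mut_aa = fit$mut_aa[i[1L]],
               type = fit$type[i[1L]], zeta = sm$mean, zeta_sd = sm$sd,
               n_codons = length(i),
               below_lower_bound = all(fit$below_lower_bound[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$beneficial <- classify_beneficial(out$zeta)
  out <- out[order(out$position, out$mut_aa, na.last = FALSE), ]
  rownames(out) <- NULL
  for (a in c("epsilon_wt", "zeta_lb", "g_p", "label")) {
    attr(out, a) <- attr(fit, a)
  }
  class(out) <- c("fitness_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
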