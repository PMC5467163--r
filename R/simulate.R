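# Competitive growth-selection simulator with known ground truth.
#
# Growth is deterministic (exponential at each lineage's relative rate); all
# stochasticity enters through multinomial read sampling of the pre- and
# post-selection populations, matching the view that counting (Poisson) noise
# dominates deep-sequencing fitness measurements.

#' Ground-truth distribution of fitness effects for the simulator
#'
#' A three-class generative stand-in for a single-substitution DFE: a point
#' mass of lethal variants (relative growth rate r = 0), a near-neutral bulk
#' (r = 1 + Gaussian noise, truncated at 0) and an exponential tail of
#' beneficial growth-rate advantages.  Nonsense variants are forced lethal
#' except within a C-terminal window where truncation is tolerated.
#'
#' @param lethal_fraction probability a variant is lethal (in `[0,1]`).
#' @param neutral_sd s.d. of the near-neutral relative growth-rate noise.
#' @param beneficial_fraction probability a variant is beneficial.
#' @param beneficial_rate rate of the exponential distribution of growth-rate
#'   advantages (mean advantage `1/beneficial_rate`); > 0.
#' @param cterm_window number of C-terminal residues where nonsense variants
#'   escape lethality (default 19).
#' @param seed mandatory integer seed; every stochastic simulator operation
#'   is reproducible.
#' @return an object of class `true_dfe_spec`.
#' @export
true_dfe_spec <- function(lethal_fraction = 0.35,
                          neutral_sd = 0.05,
                          beneficial_fraction = 0.05,
                          beneficial_rate = 7,
                          cterm_window = 19L,
                          seed) {
  if (missing(seed)) stop("invalid spec: a seed is required")
  fr <- c(lethal_fraction, beneficial_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("invalid spec: class fractions must lie in [0,1] and sum to <= 1")
  }
  if (beneficial_rate <= 0) stop("invalid spec: beneficial_rate must be > 0")
  if (neutral_sd < 0) stop("invalid spec: neutral_sd must be >= 0")
  structure(list(lethal_fraction = lethal_fraction,
                 neutral_sd = neutral_sd,
                 beneficial_fraction = beneficial_fraction,
                 beneficial_rate = beneficial_rate,
                 cterm_window = as.integer(cterm_window),
                 seed = as.integer(seed)),
            class = "true_dfe_spec")
}

#' Draw true relative growth rates for a variant universe
#'
#' Assigns every protein-level variant a class (lethal / neutral / beneficial)
#' and a true relative growth rate `r = mu_i / mu_wt`.  Synonymous codon
#' slots of one protein variant share a single `r` (fitness effects are
#' modelled at the protein level).  Nonsense variants are forced lethal
#' unless they fall within the C-terminal tolerance window, where truncation
#' is tolerated and the drawn class stands.  The wild-type member has
#' `r = 1` exactly.
#'
#' @param universe a [make_library()] data.frame (or any data.frame with
#'   `variant`, `position`, `mut_aa`, `type` columns).
#' @param spec a [true_dfe_spec()]; its `seed` drives the draw.
#' @return data.frame of class `synthetic_truth` with one row per
#'   protein-level variant: `variant`, `position`, `type`, `class`, `r`.
#' @export
sample_true_dfe <- function(universe, spec) {
  stopifnot(inherits(spec, "true_dfe_spec"))
  set.seed(spec$seed)
  prot <- unique(universe[, c("variant", "position", "mut_aa", "type")])
  n <- nrow(prot)
  L <- max(prot$position, na.rm = TRUE)
  p_leth <- spec$lethal_fraction
  p_ben <- spec$beneficial_fraction
  cls <- sample(c("lethal", "beneficial", "neutral"), n, replace = TRUE,
                prob = c(p_leth, p_ben, 1 - p_leth - p_ben))
  # nonsense: forced lethal outside the C-terminal tolerance window; inside
  # the window truncation is tolerated and the drawn class stands
  ns <- prot$type == "nonsense"
  in_window <- !is.na(prot$position) & prot$position > L - spec$cterm_window
  cls[ns & !in_window] <- "lethal"
  r <- numeric(n)
  r[cls == "lethal"] <- 0
  nn <- cls == "neutral"
  r[nn] <- pmax(0, 1 + rnorm(sum(nn), 0, spec$neutral_sd))
  bb <- cls == "beneficial"
  r[bb] <- 1 + rexp(sum(bb), spec$beneficial_rate)
  wt <- prot$type == "wt"
  cls[wt] <- "wt"
  r[wt] <- 1
  out <- data.frame(prot[, c("variant", "position", "type")],
                    class = cls, r = r, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, spec = spec, class = c("synthetic_truth", "data.frame"))
}

#' Growth-selection scenario parameters
#'
#' @param g_p total population doublings of the selection (dimensionless;
#'   the study design point is ~8).
#' @param passage_doublings doublings between harvest/re-dilution passages
#'   (in `(0, g_p]`; ~4 in the study design).  Re-dilution rescales every
#'   lineage equally, so relative frequencies — and hence fitness metrics —
#'   are unaffected; the value is recorded for provenance only.
#' @param wt_fraction_initial initial wild-type frequency (in `(0,1)`).
#' @param cheat_leak fraction of a non-grower's growth deficit rescued by
#'   cross-feeding (`0` = no cheating: a lethal lineage never increases in
#'   absolute cell number).
#' @return an object of class `selection_scenario`.
#' @export
selection_scenario <- function(g_p = 8,
                               passage_doublings = 4,
                               wt_fraction_initial = 0.3,
                               cheat_leak = 0) {
  if (g_p <= 0) stop("invalid scenario: g_p must be > 0")
  if (passage_doublings <= 0 || passage_doublings > g_p) {
    stop("invalid scenario: passage_doublings must lie in (0, g_p]")
  }
  if (wt_fraction_initial <= 0 || wt_fraction_initial >= 1) {
    stop("invalid scenario: wt_fraction_initial must lie in (0,1)")
  }
  if (cheat_leak < 0 || cheat_leak > 1) {
    stop("invalid scenario: cheat_leak must lie in [0,1]")
  }
  structure(list(g_p = g_p, passage_doublings = passage_doublings,
                 wt_fraction_initial = wt_fraction_initial,
                 cheat_leak = cheat_leak),
            class = "selection_scenario")
}

# Solve for the wild-type doublings tau at which total biomass has grown
# 2^g_p-fold.  w is the initial frequency vector, r the relative rates.
solve_gwt <- function(w, r, g_p) {
  f <- function(tau) sum(w * 2^(r * tau)) - 2^g_p
  hi <- g_p
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Simulate a competitive growth selection
#'
#' Deterministic exponential growth of every lineage at rate `r_i * mu_wt`
#' until total biomass has increased `2^g_p`-fold, followed by multinomial
#' read sampling of the pre- and post-selection populations.  Passage
#' re-dilutions rescale all lineages equally and therefore do not alter
#' relative frequencies; they are not modelled explicitly.  The realized
#' wild-type doublings `g_wt` (the root of the total-growth equation) is
#' recorded as an attribute.
#'
#' With `cheat_leak > 0` a sub-wild-type lineage recovers that fraction of
#' its growth deficit: `r_eff = r + cheat_leak * max(0, 1 - r)`.
#'
#' @param library a [make_library()] data.frame with `abundance`.
#' @param truth a [sample_true_dfe()] table aligned by `variant`.
#' @param scenario a [selection_scenario()].
#' @param depth_pre,depth_post total sequencing reads; defaults come from the
#'   library spec.
#' @param seed integer seed for the read sampling.
#' @param replicates number of sequencing/selection replicates; replicates
#'   share the deterministic growth outcome and differ only in read sampling.
#' @return data.frame of class `count_table` with columns `variant`,
#'   `position`, `wt_aa`, `mut_aa`, `codon`, `type`, `replicate`,
#'   `pre_count`, `post_count`; attributes `g_wt`, `g_p`, `seed`.
#' @examples
#' lib <- make_library(library_spec(protein_length = 5), seed = 1)
#' tr  <- sample_true_dfe(lib, true_dfe_spec(seed = 2))
#' cnt <- simulate_selection(lib, tr, selection_scenario(), seed = 3)
#' @export
simulate_selection <- function(library, truth, scenario,
                               depth_pre = NULL, depth_post = NULL,
                               seed, replicates = 1L) {
  stopifnot(inherits(scenario, "selection_scenario"))
  if (missing(seed)) stop("a seed is required")
  spec <- attr(library, "spec")
  if (is.null(depth_pre)) depth_pre <- spec$sequencing_depth_pre
  if (is.null(depth_post)) depth_post <- spec$sequencing_depth_post
  if (is.null(depth_pre) || is.null(depth_post) ||
      depth_pre <= 0 || depth_post <= 0) {
    stop("empty table: sequencing depths must be > 0")
  }
  r <- truth$r[match(library$variant, truth$variant)]
  if (anyNA(r)) {
    stop("library and truth are not aligned: ",
         paste(unique(library$variant[is.na(r)])[1:5], collapse = ", "))
  }
  ab <- library$abundance
  # rescale the wild-type member to its configured initial frequency
  wt <- library$type == "wt"
  ab[wt] <- sum(ab[!wt]) * scenario$wt_fraction_initial /
    (1 - scenario$wt_fraction_initial) / sum(wt)
  w <- ab / sum(ab)
  r_eff <- r + scenario$cheat_leak * pmax(0, 1 - r)
  g_wt <- solve_gwt(w, r_eff, scenario$g_p)
  post_w <- w * 2^(r_eff * g_wt) / 2^scenario$g_p
  # guard tiny numerical drift; multinomial needs an exact simplex
  post_w <- post_w / sum(post_w)
  set.seed(seed)
  reps <- lapply(seq_len(replicates), function(i) {
    data.frame(library[, c("variant", "position", "wt_aa", "mut_aa",
                           "codon", "type")],
               replicate = i,
               pre_count = as.integer(rmultinom(1L, depth_pre, w)),
               post_count = as.integer(rmultinom(1L, depth_post, post_w)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  structure(out, g_wt = g_wt, g_p = scenario$g_p, seed = seed,
            true_post_freq = post_w,
            class = c("count_table", "data.frame"))
}

#' Expected fitness metric of a variant with known relative growth rate
#'
#' Under deterministic exponential growth the enrichment ratio of variant i
#' is `eps_i = r_i * g_wt - g_p` (log2 of its frequency fold-change), so the
#' wild-type-normalized fitness metric is
#' `zeta = (eps_i - eps_wt)/g_p = (r_i - 1) * g_wt / g_p`.
#' For a truly dead lineage (`r = 0`) the function returns `-Inf` as a
#' sentinel: at any finite sequencing depth such lineages sit at or below the
#' detection limit, and their point estimate is not meaningful.
#'
#' @param r relative growth rate(s) `mu_i / mu_wt`.
#' @param g_wt realized wild-type doublings during the selection.
#' @param g_p total population doublings.
#' @return numeric vector of expected fitness metrics.
#' @examples
#' expected_zeta(1.1, g_wt = 12, g_p = 8)  # 0.15, the beneficial threshold
#' @export
expected_zeta <- function(r, g_wt, g_p) {
  if (g_wt <= 0 || g_p <= 0) stop("g_wt and g_p must be > 0")
  z <- (r - 1) * g_wt / g_p
  z[r == 0] <- -Inf
  z
}
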