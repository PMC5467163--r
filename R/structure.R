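# Structural context of beneficial mutations: minimum Calpha-to-active-site
# distances over all protomers of an oligomer, and distance-shell histograms
# normalized to the mutations available per shell.

#' Active-site specification for a (multimeric) structure
#'
#' Names the residues (author numbering) whose atoms constitute the active
#' site.  In a homo-oligomer the same residues recur in every protomer; all
#' copies are used unless `chains` restricts them.
#'
#' @param residues integer vector of active-site residue numbers (e.g. the
#'   catalytic nucleophile and its neighbours).
#' @param atoms optional character vector of atom names (e.g. `"SG"`);
#'   default uses every atom of the named residues.
#' @param chains optional chain identifiers to restrict the active-site
#'   copies.
#' @return object of class `active_site_spec`.
#' @export
active_site_spec <- function(residues, atoms = NULL, chains = NULL) {
  if (length(residues) < 1L) stop("at least one active-site residue required")
  structure(list(residues = as.integer(residues), atoms = atoms,
                 chains = chains),
            class = "active_site_spec")
}

#' Minimum distance from residue Calpha atoms to the active site
#'
#' For each queried position, the minimum Euclidean distance (in Angstrom)
#' between any Calpha copy of that residue (any chain, unless restricted)
#' and any active-site atom across all active-site copies.  Positions whose
#' Calpha cannot be resolved are returned as `NA` with a warning and should
#' be excluded downstream.
#'
#' @param pdb a structure from [bio3d::read.pdb()], or a path to a PDB file.
#' @param positions integer vector of residue positions (author numbering,
#'   1-based).
#' @param spec an [active_site_spec()].
#' @param position_chains optional chain restriction for the queried
#'   residues.
#' @return named numeric vector of minimum distances (names = positions).
#' @export
min_distance_to_active_site <- function(pdb, positions, spec,
                                        position_chains = NULL) {
  stopifnot(inherits(spec, "active_site_spec"))
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  as_sel <- at$resno %in% spec$residues & at$type == "ATOM"
  if (!is.null(spec$atoms)) as_sel <- as_sel & at$elety %in% spec$atoms
  if (!is.null(spec$chains)) as_sel <- as_sel & at$chain %in% spec$chains
  if (!any(as_sel)) stop("no active-site atoms resolved")
  asm <- as.matrix(at[as_sel, c("x", "y", "z")])
  out <- setNames(rep(NA_real_, length(positions)), positions)
  for (j in seq_along(positions)) {
    ca_sel <- at$resno == positions[j] & at$elety == "CA" & at$type == "ATOM"
    if (!is.null(position_chains)) {
      ca_sel <- ca_sel & at$chain %in% position_chains
    }
    if (!any(ca_sel)) next
    cam <- as.matrix(at[ca_sel, c("x", "y", "z")])
    d2 <- outer(rowSums(cam^2), rowSums(asm^2), "+") -
      2 * cam %*% t(asm)
    out[j] <- sqrt(max(0, min(d2)))
  }
  if (anyNA(out)) {
    warning("no Calpha coordinates for position(s): ",
            paste(positions[is.na(out)], collapse = ", "),
            "; returned NA")
  }
  out
}

#' Distance-shell histogram of mutations, normalized per shell
#'
#' Bins mutations by their position's minimum distance to the active site
#' into half-open shells `[k*w, (k+1)*w)` (default 3 Angstrom wide) and
#' normalizes each shell's count by the mutations available there: by
#' default 19 missense possibilities per residue position in the shell, or
#' the assayed per-position counts when supplied.
#'
#' @param distances named numeric vector from
#'   [min_distance_to_active_site()] covering every relevant position
#'   (names = positions).
#' @param mutation_positions integer vector, one entry per mutation of
#'   interest (positions may repeat).
#' @param bin_width shell width in Angstrom (default 3).
#' @param available optional named vector of assayed mutation counts per
#'   position; default `19` per position (saturation missense).
#' @return data.frame with `shell_lo`, `shell_hi`, `n_mutations`,
#'   `n_available`, `fraction`; shells with no available mutations are
#'   absent, and raw counts sum to `length(mutation_positions)`.
#' @export
shell_histogram <- function(distances, mutation_positions, bin_width = 3,
                            available = NULL) {
  pos <- as.integer(names(distances))
  if (anyNA(distances)) stop("distances contain NA; exclude those positions")
  miss <- setdiff(unique(mutation_positions), pos)
  if (length(miss)) {
    stop("no distance for mutation position(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(available)) {
    avail <- setNames(rep(19, length(pos)), pos)
  } else {
    avail <- available[as.character(pos)]
    if (anyNA(avail)) stop("available counts missing for some positions")
  }
  shell_of <- function(d) floor(d / bin_width)
  pos_shell <- shell_of(distances)
  mut_shell <- pos_shell[match(as.character(mutation_positions),
                               names(distances))]
  shells <- sort(unique(pos_shell))
  rows <- lapply(shells, function(s) {
    n_av <- sum(avail[pos_shell == s])
    data.frame(shell_lo = s * bin_width, shell_hi = (s + 1) * bin_width,
               n_mutations = sum(mut_shell == s), n_available = n_av,
               fraction = sum(mut_shell == s) / n_av)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
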