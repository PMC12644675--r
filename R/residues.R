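# Monoisotopic element masses (u), 1997 IUPAC values to >= 5 decimals.
.element_monoisotopic <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Average (standard atomic weight) masses, u.
.element_average <- c(
  C = 12.011,
  H = 1.008,
  N = 14.007,
  O = 15.999,
  S = 32.06
)

#' Mass of a proton used for m/z calculation (u)
#' @keywords internal
.proton_mass <- 1.00728

# Residue (backbone + side chain, minus water) elemental compositions.
# Rows: C, H, N, O, S.  Multi-letter tokens are the non-natural residues:
# Nal = 3-(2-naphthyl)alanine, Dip = 3,3-diphenylalanine.
.residue_formulas <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0),
  Nal = c(C = 13, H = 11, N = 1, O = 1, S = 0),
  Dip = c(C = 15, H = 13, N = 1, O = 1, S = 0)
)

.formula_mass <- function(formula, masses = .element_monoisotopic) {
  el <- names(formula)
  if (!all(el %in% names(masses))) {
    stop("no mass known for element(s): ",
         paste(setdiff(el, names(masses)), collapse = ", "))
  }
  sum(formula * masses[el])
}

#' Residue mass and composition table
#'
#' Returns the built-in table of amino acid residues (the 20 canonical
#' residues plus the non-natural residues `Nal`, 3-(2-naphthyl)alanine, and
#' `Dip`, 3,3-diphenylalanine) with their elemental compositions and
#' monoisotopic and average residue masses.  Residue means backbone plus side
#' chain minus water, i.e. the mass each position contributes to a peptide
#' chain.  D-stereoisomers (written in lowercase in sequence strings) have
#' identical formula and mass and therefore do not appear as separate rows.
#'
#' @param custom_residues optional named list of extra residues; each element
#'   is a named numeric vector of element counts over C, H, N, O, S (missing
#'   elements default to 0).  Use this to register residues such as the
#'   bicyclic Hot/Tap units, which are not built in.
#' @return a `data.frame` with columns `token`, `C`, `H`, `N`, `O`, `S`,
#'   `monoisotopic_mass`, `average_mass`.
#' @examples
#' head(residue_table())
#' residue_table(custom_residues = list(Xyz = c(C = 5, H = 7, N = 1, O = 2)))
#' @export
residue_table <- function(custom_residues = NULL) {
  formulas <- .residue_formulas
  if (!is.null(custom_residues)) {
    if (is.null(names(custom_residues)) || any(!nzchar(names(custom_residues))))
      stop("custom_residues must be a named list")
    for (nm in names(custom_residues)) {
      f <- custom_residues[[nm]]
      full <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
      full[names(f)] <- f
      formulas[[nm]] <- full
    }
  }
  tab <- do.call(rbind, lapply(formulas, function(f) as.data.frame(as.list(f))))
  tab <- data.frame(token = names(formulas), tab, row.names = NULL)
  tab$monoisotopic_mass <- vapply(
    formulas, .formula_mass, numeric(1), masses = .element_monoisotopic)
  tab$average_mass <- vapply(
    formulas, .formula_mass, numeric(1), masses = .element_average)
  tab
}

#' Amino acid sequences of the seven engineered foldon trimerization domains
#'
#' The 27-residue trimerization domain of bacteriophage T4 fibritin (the
#' "foldon", variant 0) and six chemically engineered variants.  Lowercase
#' letters denote D-amino acid residues, brace-delimited tokens the
#' non-natural residues, and the terminal markers distinguish the free-acid
#' from the C-terminally amidated peptides.  These sequences drive all worked
#' examples and the synthetic-data defaults.
#'
#' @return named character vector (`foldon0` ... `foldon6`).
#' @examples
#' foldon_sequences()[["foldon0"]]
#' @export
foldon_sequences <- function() {
  c(
    foldon0 = "H-GYIPEAPRDGQAYVRKDGEWVLLSTFL-OH",
    foldon1 = "H-GYIPEAPRDaQAYVRKfGEWVLLSTFL-NH2",
    foldon2 = "H-GyIPEAPRDaQAYVRKfGEWVLLSTFL-NH2",
    foldon3 = "H-YIPEAPRDaQAYVRKfGEWVLLSTFL-NH2",
    foldon4 = "H-yIPEAPRDaQAYVRKfGEWVLLSTFL-NH2",
    foldon5 = "H-{Nal}IPEAPRDaQAYVRKfGEWVLLSTFL-NH2",
    foldon6 = "H-{Dip}IPEAPRDaQAYVRKfGEWVLLSTFL-NH2"
  )
}
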