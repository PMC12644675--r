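#' Parse a peptide sequence string
#'
#' Parses sequences written in single-letter code with lowercase letters for
#' D-amino acid residues and brace-delimited multi-letter tokens for
#' non-natural residues (e.g. `"{Nal}"`, `"{Dip}"`).  An optional `H-` prefix
#' marks the free N-terminal amine and an optional `-OH` / `-NH2` suffix
#' selects the free-acid or carboxamide C-terminus (default acid).
#' Stereochemistry is preserved for reporting but is mass-neutral: a D-residue
#' has the same formula and mass as its L-counterpart.
#'
#' @param text sequence string, e.g. `"H-GYIPEAPRDGQAYVRKDGEWVLLSTFL-OH"`.
#' @param custom_residues passed to [residue_table()] to register additional
#'   residue tokens.
#' @return an object of class `peptide_sequence`: a list with `residues`
#'   (canonical residue tokens), `stereo` (`"L"`/`"D"` per position),
#'   `n_terminus`, `c_terminus` (`"acid"` or `"amide"`), and the original
#'   `text`.
#' @examples
#' seq0 <- parse_sequence(foldon_sequences()[["foldon0"]])
#' length(seq0$residues)  # 27
#' parse_sequence("H-{Dip}IPEAPRDaQAYVRKfGEWVLLSTFL-NH2")$c_terminus
#' @export
parse_sequence <- function(text, custom_residues = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("sequence must be a single non-empty string")
  tab <- residue_table(custom_residues)
  body <- text

  n_terminus <- "free-amine"
  if (grepl("^H-", body)) body <- sub("^H-", "", body)

  c_terminus <- "acid"
  if (grepl("-NH2$", body, ignore.case = TRUE)) {
    c_terminus <- "amide"
    body <- sub("-NH2$", "", body, ignore.case = TRUE)
  } else if (grepl("-OH$", body, ignore.case = TRUE)) {
    body <- sub("-OH$", "", body, ignore.case = TRUE)
  }
  if (!nzchar(body)) stop("sequence contains no residues")

  m <- gregexpr("\\{[A-Za-z][A-Za-z0-9]*\\}|.", body)[[1]]
  tokens <- regmatches(body, list(m))[[1]]
  residues <- character(length(tokens))
  stereo <- character(length(tokens))
  pos_in_string <- as.integer(m)

  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (startsWith(tok, "{")) {
      tok <- substr(tok, 2L, nchar(tok) - 1L)
      if (!tok %in% tab$token)
        stop(sprintf("unknown residue token '{%s}' at position %d", tok, i))
      residues[i] <- tok
      stereo[i] <- "L"
    } else if (grepl("^[A-Z]$", tok)) {
      if (!tok %in% tab$token)
        stop(sprintf("unknown residue token '%s' at position %d", tok, i))
      residues[i] <- tok
      stereo[i] <- "L"
    } else if (grepl("^[a-z]$", tok)) {
      up <- toupper(tok)
      if (!up %in% tab$token)
        stop(sprintf("unknown residue token '%s' at position %d", tok, i))
      residues[i] <- up
      stereo[i] <- "D"
    } else {
      stop(sprintf("unknown character '%s' at string offset %d",
                   tok, pos_in_string[i]))
    }
  }

  structure(
    list(residues = residues, stereo = stereo,
         n_terminus = n_terminus, c_terminus = c_terminus,
         text = text, residue_table = tab),
    class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  shown <- ifelse(x$stereo == "D", tolower(x$residues),
                  ifelse(nchar(x$residues) > 1L,
                         paste0("{", x$residues, "}"), x$residues))
  cat(sprintf("<peptide_sequence> %d residues, %s C-terminus\n",
              length(x$residues), x$c_terminus))
  cat(" ", paste(shown, collapse = ""), "\n")
  invisible(x)
}

.as_peptide <- function(seq) {
  if (inherits(seq, "peptide_sequence")) seq else parse_sequence(seq)
}

#' Molecular formula and atom count of a peptide
#'
#' Element-wise sum of the residue formulas plus one water for the intact
#' chain; a C-terminal amide replaces OH by NH2 (net -O +N +H).  For n-mers
#' the formula is simply multiplied: the oligomers are non-covalent, no mass
#' is lost on assembly.
#'
#' @param seq a `peptide_sequence` or a sequence string.
#' @param n_mer number of monomer copies (default 1).
#' @return named integer vector of element counts with attribute
#'   `"atom_count"` (total number of atoms, hydrogens included).
#' @examples
#' f <- molecular_formula("H-G-OH")   # glycine, C2H5NO2
#' attr(f, "atom_count")              # 10
#' @export
molecular_formula <- function(seq, n_mer = 1L) {
  seq <- .as_peptide(seq)
  if (n_mer < 1) stop("n_mer must be >= 1")
  tab <- seq$residue_table
  idx <- match(seq$residues, tab$token)
  els <- c("C", "H", "N", "O", "S")
  counts <- colSums(tab[idx, els, drop = FALSE])
  counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # + H2O
  if (seq$c_terminus == "amide")
    counts <- counts + c(C = 0, H = 1, N = 1, O = -1, S = 0)
  counts <- counts * n_mer
  counts <- vapply(counts, as.integer, integer(1))
  structure(counts, atom_count = sum(counts))
}

#' Atom count of a peptide n-mer
#'
#' @inheritParams molecular_formula
#' @return integer total number of atoms (hydrogens included).
#' @export
atom_count <- function(seq, n_mer = 1L) {
  attr(molecular_formula(seq, n_mer), "atom_count")
}

#' Monoisotopic (or average) mass of a peptide
#'
#' Sum of residue masses plus water (18.01056 u), minus 0.98402 u for a
#' C-terminal amide.  Stereochemistry is ignored: D-residues weigh the same
#' as their L-counterparts.
#'
#' @inheritParams molecular_formula
#' @param kind `"monoisotopic"` (default; the convention used for calculated
#'   m/z tables) or `"average"`.
#' @return mass in u.
#' @examples
#' monoisotopic_mass("H-G-OH")  # 75.03203
#' @export
monoisotopic_mass <- function(seq, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  seq <- .as_peptide(seq)
  tab <- seq$residue_table
  idx <- match(seq$residues, tab$token)
  col <- if (kind == "monoisotopic") "monoisotopic_mass" else "average_mass"
  masses <- if (kind == "monoisotopic") .element_monoisotopic else .element_average
  water <- 2 * masses[["H"]] + masses[["O"]]
  m <- sum(tab[[col]][idx]) + water
  if (seq$c_terminus == "amide")
    m <- m - masses[["O"]] + masses[["N"]] + masses[["H"]]
  m
}

#' m/z of a multiply protonated non-covalent n-mer ion
#'
#' `(n_mer * M + z * 1.00728 + adduct_mass) / z` with M the monomer
#' monoisotopic mass.  Oligomer assembly is non-covalent, so the n-mer
#' neutral mass is exactly `n_mer * M`.
#'
#' @inheritParams molecular_formula
#' @param z positive charge (number of protons).
#' @param adduct_mass optional extra neutral adduct mass carried by the ion
#'   (e.g. sodium-for-proton exchange satellites); default 0.
#' @return m/z in u per charge.
#' @examples
#' oligomer_mz("H-G-OH", n_mer = 1, z = 1)                      # 76.039 (M+H)+
#' oligomer_mz(foldon_sequences()[["foldon0"]], n_mer = 3, z = 5) # 1848.75
#' @export
oligomer_mz <- function(seq, n_mer = 1L, z = 1L, adduct_mass = 0) {
  if (z < 1) stop("z must be a positive integer: a neutral has no m/z")
  if (n_mer < 1) stop("n_mer must be >= 1")
  (n_mer * monoisotopic_mass(seq) + z * .proton_mass + adduct_mass) / z
}

#' Mass table for a batch of peptides
#'
#' Convenience wrapper producing one row per analyte with monomer mass,
#' formula string, atom counts and the n-mer m/z, in the shape of a
#' sequence-characterization table.
#'
#' @param sequences named character vector of sequence strings.
#' @param n_mer,z oligomer size and charge for the reported m/z.
#' @return data.frame with columns `name`, `n_residues`, `monomer_mass`,
#'   `formula`, `atoms_monomer`, `atoms_nmer`, `mz`.
#' @examples
#' mass_table(foldon_sequences(), n_mer = 3, z = 5)
#' @export
mass_table <- function(sequences, n_mer = 3L, z = 5L) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (is.null(names(sequences))) names(sequences) <- seq_along(sequences)
  rows <- lapply(names(sequences), function(nm) {
    p <- parse_sequence(sequences[[nm]])
    f <- molecular_formula(p)
    fstr <- paste0(names(f)[f > 0], f[f > 0], collapse = "")
    data.frame(
      name = nm,
      n_residues = length(p$residues),
      monomer_mass = monoisotopic_mass(p),
      formula = fstr,
      atoms_monomer = as.integer(attr(f, "atom_count")),
      atoms_nmer = as.integer(attr(f, "atom_count") * n_mer),
      mz = oligomer_mz(p, n_mer = n_mer, z = z))
  })
  do.call(rbind, rows)
}
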