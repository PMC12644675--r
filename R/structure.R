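#' Construct a structure model from an atom table
#'
#' Minimal coordinate container used by the interface-metric operations:
#' one row per atom with chain label, residue number and name, atom name,
#' element symbol and Cartesian coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`.
#' @return data.frame of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  atoms <- atoms[, need]
  rownames(atoms) <- NULL
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Read a PDB-format coordinate file
#'
#' Thin wrapper over `bio3d::read.pdb()` returning a [structure_model()].
#' Waters are excluded by default; alternate locations are resolved by
#' keeping the highest-occupancy conformer of each atom.  For multi-model
#' (NMR) entries the first model is used.  Element symbols missing from the
#' file are inferred from the atom name.
#'
#' @param path PDB file path.
#' @param keep_waters keep water molecules (default FALSE).
#' @param keep_hetatm keep non-water HETATM records (default FALSE).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, keep_waters = FALSE, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM" |
                               at$resid %in% c("HOH", "WAT"), , drop = FALSE]
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms retained from ", path)
  # altloc: keep the highest-occupancy conformer per (chain, resno, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elesy <- at$elesy
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  if (any(bad)) {
    guess <- toupper(substr(gsub("[0-9]", "", at$elety[bad]), 1, 1))
    elesy[bad] <- guess
  }
  structure_model(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety, elesy = trimws(elesy),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Contact classification criteria
#'
#' Distance cutoffs (Angstrom) for the three monitored non-covalent force
#' types.  The 4.0 A default for carbon-carbon (van der Waals / hydrophobic)
#' contacts follows the standard intercatenane-contact criterion; hydrogen
#' bonds use a heavy-atom donor-acceptor cutoff (no angle term, since
#' crystallographic entries typically lack hydrogens).
#'
#' @param vdw_cutoff carbon-carbon contact cutoff (default 4.0).
#' @param hbond_cutoff N/O heavy-atom donor-acceptor cutoff (default 3.5).
#' @param saltbridge_cutoff carboxylate-to-basic-group cutoff (default 4.0).
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(vdw_cutoff = 4.0, hbond_cutoff = 3.5,
                             saltbridge_cutoff = 4.0) {
  if (any(c(vdw_cutoff, hbond_cutoff, saltbridge_cutoff) <= 0))
    stop("cutoffs must be positive")
  structure(list(vdw_cutoff = vdw_cutoff, hbond_cutoff = hbond_cutoff,
                 saltbridge_cutoff = saltbridge_cutoff),
            class = "contact_criteria")
}

# all unordered atom pairs (i < j over the model row index) between index
# sets a and b with distance <= cutoff; excludes same-residue pairs and,
# when exclude_adjacent, same-chain pairs of directly neighboring residues
# (|resno difference| <= 1), a proxy for bonded and 1-3 neighborhoods.
.contact_pairs <- function(model, a, b, cutoff, exclude_adjacent = TRUE) {
  if (length(a) == 0 || length(b) == 0) return(NULL)
  xa <- as.matrix(model[a, c("x", "y", "z")])
  xb <- as.matrix(model[b, c("x", "y", "z")])
  out <- vector("list", length(a))
  for (k in seq_along(a)) {
    d2 <- (xb[, 1] - xa[k, 1])^2 + (xb[, 2] - xa[k, 2])^2 + (xb[, 3] - xa[k, 3])^2
    hit <- which(d2 <= cutoff^2 & b > a[k])
    if (length(hit) == 0) next
    i <- a[k]; j <- b[hit]
    same_res <- model$chain[j] == model$chain[i] & model$resno[j] == model$resno[i]
    keep <- !same_res
    if (exclude_adjacent) {
      adj <- model$chain[j] == model$chain[i] &
        abs(model$resno[j] - model$resno[i]) <= 1
      keep <- keep & !adj
    }
    j <- j[keep]
    if (length(j) == 0) next
    out[[k]] <- data.frame(
      i = i, j = j, distance = sqrt(d2[hit][keep]),
      scope = ifelse(model$chain[j] == model$chain[i], "intra", "inter"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

.describe_pairs <- function(model, pairs, type) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(type = character(), chain1 = character(), resno1 = integer(),
                      resid1 = character(), atom1 = character(),
                      chain2 = character(), resno2 = integer(),
                      resid2 = character(), atom2 = character(),
                      distance = numeric(), scope = character()))
  }
  data.frame(
    type = type,
    chain1 = model$chain[pairs$i], resno1 = model$resno[pairs$i],
    resid1 = model$resid[pairs$i], atom1 = model$elety[pairs$i],
    chain2 = model$chain[pairs$j], resno2 = model$resno[pairs$j],
    resid2 = model$resid[pairs$j], atom2 = model$elety[pairs$j],
    distance = pairs$distance, scope = pairs$scope,
    stringsAsFactors = FALSE)
}

#' Classify intra- vs intercatenane non-covalent contacts
#'
#' Enumerates unique unordered atom pairs within the per-type cutoffs and
#' labels each pair intracatenane (same chain) or intercatenane (different
#' chains):
#' \itemize{
#'   \item van der Waals: carbon-carbon pairs, excluding pairs within one
#'     residue or between directly neighboring residues of the same chain;
#'   \item hydrogen bonds: N/O heavy-atom pairs (donor-acceptor, no angle
#'     term), same exclusions;
#'   \item salt bridges: Asp/Glu carboxylate oxygens (and C-terminal OXT) to
#'     Arg/Lys/His basic nitrogens.
#' }
#'
#' @param model a [structure_model()].
#' @param criteria a [contact_criteria()].
#' @return list of class `contact_table` with `pairs` (one data.frame of all
#'   contributing pairs) and `summary` (data.frame with `type`, `intra`,
#'   `inter`, `total`).
#' @export
classify_contacts <- function(model, criteria = contact_criteria()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(criteria, "contact_criteria"))
  carbons <- which(model$elesy == "C")
  vdw <- .contact_pairs(model, carbons, carbons, criteria$vdw_cutoff)

  polar <- which(model$elesy %in% c("N", "O"))
  hb <- .contact_pairs(model, polar, polar, criteria$hbond_cutoff)

  acid <- which((model$resid == "ASP" & model$elety %in% c("OD1", "OD2")) |
                  (model$resid == "GLU" & model$elety %in% c("OE1", "OE2")) |
                  model$elety == "OXT")
  base <- which((model$resid == "ARG" & model$elety %in% c("NH1", "NH2", "NE")) |
                  (model$resid == "LYS" & model$elety == "NZ") |
                  (model$resid == "HIS" & model$elety %in% c("ND1", "NE2")))
  sb <- .contact_pairs(model, sort(c(acid, base)), sort(c(acid, base)),
                       criteria$saltbridge_cutoff)
  if (!is.null(sb)) {
    # keep only acid-base pairs (not acid-acid / base-base)
    ok <- (sb$i %in% acid & sb$j %in% base) | (sb$i %in% base & sb$j %in% acid)
    sb <- sb[ok, , drop = FALSE]
  }

  pairs <- rbind(.describe_pairs(model, vdw, "vdW"),
                 .describe_pairs(model, hb, "hydrogen bond"),
                 .describe_pairs(model, sb, "salt bridge"))
  summ <- do.call(rbind, lapply(c("vdW", "hydrogen bond", "salt bridge"),
    function(tp) {
      sub <- pairs[pairs$type == tp, , drop = FALSE]
      data.frame(type = tp,
                 intra = sum(sub$scope == "intra"),
                 inter = sum(sub$scope == "inter"),
                 total = nrow(sub))
    }))
  structure(list(pairs = pairs, summary = summ, criteria = criteria),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat("<contact_table>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-position interchain C-alpha distances of a trimer
#'
#' For every residue position shared by the three chains, the three pairwise
#' distances between the C-alpha atoms of that position in the different
#' chains, their mean and standard deviation, and the global sum over all
#' positions and pairs.  Chains are matched by position after renumbering
#' each chain from its first resolved residue.
#'
#' @param model a `structure_model` with exactly 3 chains.
#' @return list of class `ca_distance_stats` with `per_position`
#'   (data.frame: position, resid, d12, d13, d23, mean, sd) and `total_sum`
#'   (Angstrom).
#' @export
ca_distance_stats <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  chains <- sort(unique(model$chain))
  if (length(chains) != 3)
    stop("trimer operation requires exactly 3 chains, found ", length(chains))
  ca <- model[model$elety == "CA", , drop = FALSE]
  perch <- lapply(chains, function(ch) {
    sub <- ca[ca$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$resno), , drop = FALSE]
    sub$position <- seq_len(nrow(sub))
    sub
  })
  ns <- vapply(perch, nrow, integer(1))
  n <- min(ns)
  if (length(unique(ns)) > 1) {
    extra <- unlist(lapply(seq_along(chains), function(i)
      if (ns[i] > n) sprintf("(%s, position %s)", chains[i],
                             paste((n + 1):ns[i], collapse = ",")) else NULL))
    stop("chains have unmatched residue sets; unpaired: ",
         paste(extra, collapse = "; "))
  }
  rows <- lapply(seq_len(n), function(p) {
    xyz <- t(vapply(perch, function(sub)
      unlist(sub[sub$position == p, c("x", "y", "z")]), numeric(3)))
    d <- c(d12 = sqrt(sum((xyz[1, ] - xyz[2, ])^2)),
           d13 = sqrt(sum((xyz[1, ] - xyz[3, ])^2)),
           d23 = sqrt(sum((xyz[2, ] - xyz[3, ])^2)))
    data.frame(position = p, resid = perch[[1]]$resid[p],
               d12 = d[1], d13 = d[2], d23 = d[3],
               mean = mean(d), sd = stats::sd(d))
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  structure(list(per_position = per,
                 total_sum = sum(per$d12 + per$d13 + per$d23)),
            class = "ca_distance_stats")
}

#' @export
print.ca_distance_stats <- function(x, ...) {
  cat(sprintf("<ca_distance_stats> %d positions, sum of interchain CA distances = %.2f A\n",
              nrow(x$per_position), x$total_sum))
  invisible(x)
}
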