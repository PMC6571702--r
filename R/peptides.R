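#' Built-in Histatin 5 variant library
#'
#' Histatin 5 (Hst5) is a 24-residue histidine-rich salivary peptide. Five
#' engineered variants modulate the number and placement of histidines, which
#' mediate Zn2+ binding: histidines are substituted by glutamine, a
#' pH-insensitive histidine analogue of similar size. The wild type carries
#' two histidine-rich motifs: a zinc-binding-like motif HAKRHH near the
#' N-terminus (H3, H7, H8) and the canonical HExxH zinc motif HEKHH
#' (H15, E16, H18, H19).
#'
#' Variants:
#' \describe{
#'   \item{WT}{wild-type Hst5, 7 histidines.}
#'   \item{RAN}{randomised sequence, same composition, 7 histidines, no
#'     intact HExxH motif.}
#'   \item{DZM}{zinc-motif histidines (H15, H18, H19) replaced by Gln; 4 His.}
#'   \item{ZM}{histidines outside the zinc motif (H3, H7, H8, H21) replaced
#'     by Gln, leaving the HExxH motif intact; 3 His.}
#'   \item{2H}{only H7 and H18 retained; 2 His, motif broken.}
#'   \item{DH}{all histidines replaced by Gln; 0 His.}
#' }
#'
#' @return A tibble with columns `name`, `sequence`, `n_his`, `description`.
#' @export
#' @examples
#' hst5_variants()
hst5_variants <- function() {
  tibble::tibble(
    name = c("WT", "RAN", "DZM", "ZM", "2H", "DH"),
    sequence = c(
      "DSHAKRHHGYKRKFHEKHHSHRGY",
      "HKRHGYSHKDHAFHEKHRYKSHRG",
      "DSHAKRHHGYKRKFQEKQQSHRGY",
      "DSQAKRQQGYKRKFHEKHHSQRGY",
      "DSQAKRHQGYKRKFQEKHQSQRGY",
      "DSQAKRQQGYKRKFQEKQQSQRGY"
    ),
    n_his = c(7L, 7L, 4L, 3L, 2L, 0L),
    description = c(
      "wild-type Histatin 5",
      "randomised sequence, histidine count preserved",
      "zinc-motif histidines removed (H15, H18, H19 -> Q)",
      "zinc-binding-like motif histidines removed (H3, H7, H8, H21 -> Q)",
      "two histidines retained (H7, H18)",
      "all histidines replaced by glutamine"
    )
  )
}

#' Build a peptide definition
#'
#' Constructs the bead-model definition for wild-type Hst5 or one of the
#' five variants: the sequence, histidine count and the "sticky" residue set
#' that carries the implicit-zinc short-ranged attraction (all histidines,
#' plus the motif glutamate E16 when the HExxH zinc motif is intact).
#'
#' @param name One of `"WT"`, `"RAN"`, `"DZM"`, `"ZM"`, `"2H"`, `"DH"`.
#' @return An object of class `"peptide"`: a list with `name`, `sequence`,
#'   `residues` (character vector), `n_his`, `sticky_residues` (1-based
#'   residue indices active when zinc is present), `motif_intact` (logical).
#' @export
#' @examples
#' wt <- build_peptide("WT")
#' wt$n_his
build_peptide <- function(name) {
  lib <- hst5_variants()
  if (!is.character(name) || length(name) != 1L || !(name %in% lib$name)) {
    stop("unknown variant '", paste(name, collapse = ","),
         "'; valid names: ", paste(lib$name, collapse = ", "), call. = FALSE)
  }
  row <- lib[lib$name == name, ]
  res <- strsplit(row$sequence, "")[[1]]
  his <- which(res == "H")
  stopifnot(length(his) == row$n_his)
  motif <- .has_hexxh(res)
  sticky <- sort(unique(c(his, if (motif$intact) motif$glu)))
  structure(
    list(
      name = name, sequence = row$sequence, residues = res,
      n_his = length(his), sticky_residues = sticky,
      motif_intact = motif$intact
    ),
    class = "peptide"
  )
}

# Locate an intact HExxH motif; returns the glutamate residue index
.has_hexxh <- function(res) {
  n <- length(res)
  for (i in seq_len(max(0L, n - 4L))) {
    if (res[i] == "H" && res[i + 1L] == "E" && res[i + 4L] == "H") {
      return(list(intact = TRUE, glu = i + 1L))
    }
  }
  list(intact = FALSE, glu = integer(0))
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$name, ": ", x$sequence, "\n", sep = "")
  cat("  histidines: ", x$n_his,
      "; sticky residues (with Zn2+): ",
      if (length(x$sticky_residues)) paste(x$sticky_residues, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Assign per-bead valences
#'
#' The bead chain represents each residue as one bead plus two explicit
#' terminal beads carrying the N-terminal (+1) and C-terminal (-1) charges,
#' so a peptide of L residues maps to L + 2 beads. Asp/Glu are -1, Lys/Arg
#' +1. Histidine is neutral at pH 6.7 (pKa ~ 6) in `"neutral-his"` mode and
#' +1 in `"protonated-his"` mode (the pH 4 control, where zinc-induced
#' oligomerisation is abolished).
#'
#' @param peptide A `"peptide"` object from [build_peptide()].
#' @param ph_mode `"neutral-his"` (pH 6.7, default) or `"protonated-his"`
#'   (pH 4).
#' @return Integer vector of valences, length `length(residues) + 2`:
#'   N-terminal bead, residue beads, C-terminal bead.
#' @export
#' @examples
#' sum(assign_charges(build_peptide("WT")))  # net charge +5 at pH 6.7
assign_charges <- function(peptide, ph_mode = c("neutral-his", "protonated-his")) {
  stopifnot(inherits(peptide, "peptide"))
  ph_mode <- match.arg(ph_mode)
  res <- peptide$residues
  unknown <- setdiff(unique(res), names(.residue_mass))
  if (length(unknown)) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  z <- integer(length(res))
  z[res %in% c("D", "E")] <- -1L
  z[res %in% c("K", "R")] <- 1L
  if (ph_mode == "protonated-his") z[res == "H"] <- 1L
  c(1L, z, -1L)
}

#' Sticky (implicit-zinc) bead set
#'
#' Beads carrying the strengthened short-ranged attraction that models
#' Zn2+-mediated association: all histidines plus the motif glutamate when
#' the HExxH motif is intact. Without zinc the set is empty.
#'
#' @param peptide A `"peptide"` object.
#' @param zinc_present Logical; is Zn2+ present?
#' @return Integer vector of bead indices (1-based, in the L + 2 bead
#'   numbering that includes the terminal beads). Empty when
#'   `zinc_present = FALSE` or no sticky residues remain.
#' @export
#' @examples
#' sticky_set(build_peptide("WT"), zinc_present = TRUE)
sticky_set <- function(peptide, zinc_present) {
  stopifnot(inherits(peptide, "peptide"), is.logical(zinc_present))
  if (!zinc_present) return(integer(0))
  peptide$sticky_residues + 1L  # shift by the N-terminal bead
}

#' Peptide molar mass
#'
#' Average molar mass computed from residue masses plus one water.
#'
#' @param peptide A `"peptide"` object.
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(peptide) {
  stopifnot(inherits(peptide, "peptide"))
  sum(.residue_mass[peptide$residues]) + .water_mass
}

#' Bead-chain topology for a peptide
#'
#' All beads are hard spheres of radius 2 A connected by harmonic bonds with
#' equilibrium separation 4.1 A; the two terminal beads are bonded to the
#' first and last residue beads.
#'
#' @param peptide A `"peptide"` object.
#' @param ph_mode Passed to [assign_charges()].
#' @param zinc_present Logical; activates the sticky bead set.
#' @return A list with `n_beads`, `radii` (A), `charges`, `sticky`
#'   (logical per bead), `bonds` (two-column matrix of consecutive pairs).
#' @export
bead_chain <- function(peptide, ph_mode = "neutral-his", zinc_present = FALSE) {
  z <- assign_charges(peptide, ph_mode)
  n <- length(z)
  sticky <- rep(FALSE, n)
  sticky[sticky_set(peptide, zinc_present)] <- TRUE
  list(
    n_beads = n,
    radii = rep(2.0, n),
    charges = z,
    sticky = sticky,
    bonds = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  )
}

#' Place peptide chains in a periodic box
#'
#' Builds an initial configuration of `n_chains` copies of the peptide
#' (or a count derived from a target mass concentration) in a cubic
#' periodic box, each chain grown as a self-avoiding walk with bond length
#' 4.1 A from a random origin, with no hard-sphere overlap anywhere in the
#' system (minimum-image convention).
#'
#' @param peptide A `"peptide"` object.
#' @param box_length Box edge in A.
#' @param concentration Target mass concentration in mg/mL. The chain count
#'   is `round(c * V * NA / M)`. Ignored when `n_chains` is given.
#' @param n_chains Explicit chain count (overrides `concentration`).
#' @param ph_mode,zinc_present Passed to [bead_chain()].
#' @param seed Integer seed; configurations are reproducible.
#' @param max_tries Placement retries per chain before erroring.
#' @return An object of class `"mc_system"`: list with `coords` (N x 3
#'   matrix, A, unwrapped), `box_length`, `n_chains`, `chain` (the
#'   [bead_chain()]), `peptide`, `concentration` (mg/mL implied by the
#'   final chain count).
#' @export
#' @examples
#' sys <- build_system(build_peptide("WT"), box_length = 450,
#'                     n_chains = 2, seed = 1)
#' sys$n_chains
build_system <- function(peptide, box_length, concentration = NULL,
                         n_chains = NULL, ph_mode = "neutral-his",
                         zinc_present = FALSE, seed = NULL,
                         max_tries = 2000L) {
  stopifnot(inherits(peptide, "peptide"), box_length > 0)
  chain <- bead_chain(peptide, ph_mode, zinc_present)
  if (is.null(n_chains)) {
    if (is.null(concentration) || concentration <= 0) {
      stop("supply a positive `concentration` or an explicit `n_chains`",
           call. = FALSE)
    }
    vol_ml <- (box_length * 1e-8)^3           # cm^3
    mass_g <- concentration * 1e-3 * vol_ml   # mg/mL * mL -> g
    n_chains <- as.integer(round(mass_g / molar_mass(peptide) * .avogadro))
    if (n_chains < 1L) stop("concentration too low: zero chains", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  coords <- place_chains_cpp(n_chains, chain$n_beads, box_length,
                             r0 = 4.1, contact = 4.0,
                             max_tries = as.integer(max_tries))
  if (is.null(dim(coords))) {
    stop("could not place ", n_chains, " chains without overlap in a ",
         box_length, " A box after ", max_tries, " tries per chain",
         call. = FALSE)
  }
  vol_ml <- (box_length * 1e-8)^3
  structure(
    list(
      coords = coords, box_length = box_length, n_chains = n_chains,
      chain = chain, peptide = peptide,
      ph_mode = ph_mode, zinc_present = zinc_present,
      concentration = n_chains * molar_mass(peptide) / .avogadro / vol_ml * 1e3
    ),
    class = "mc_system"
  )
}

#' @export
print.mc_system <- function(x, ...) {
  cat("<mc_system> ", x$n_chains, " chain(s) of ", x$peptide$name,
      " (", x$chain$n_beads, " beads each) in a ", x$box_length,
      " A periodic box\n", sep = "")
  cat(sprintf("  concentration %.3g mg/mL; zinc %s; %s mode\n",
              x$concentration, if (x$zinc_present) "present" else "absent",
              x$ph_mode))
  invisible(x)
}
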