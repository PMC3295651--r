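#' Default clade signature specifications
#'
#' Position-to-residue maps used by [simulate_family_sequences()] to plant
#' clade-diagnostic residues, built from the packaged signature profiles.
#' The GbpA clade carries the full GbpA profile; the DppA clade carries the
#' DppA profile (positions read as plain sequence positions in the shared
#' synthetic coordinate system); the HbpA2 clade carries the GbpA profile
#' with the literature-described incompatible substitutions (R33T, A380P,
#' S430T, D432R) plus an arginine at the DppA salt-bridge position (D408R),
#' so that HbpA2-clade members conserve 10 of the 13 C-lobe GbpA signature
#' positions and trip the salt-bridge incompatibility flags.
#'
#' @param profiles Named list of [signature_profile]s (default the packaged
#'   ones).
#' @return Named list of named character vectors (names = positions).
#' @export
default_family_signatures <- function(profiles = build_default_profiles()) {
  as_map <- function(p) setNames(p$ref_residue, p$ref_position)
  gbpa <- as_map(profiles$GbpA)
  dppa <- as_map(profiles$DppA)
  hbpa2 <- gbpa
  hbpa2[c("33", "380", "430", "432")] <- c("T", "P", "T", "R")
  hbpa2 <- c(hbpa2, "408" = "R")
  hbpa2 <- hbpa2[order(as.integer(names(hbpa2)))]
  list(GbpA = gbpa, DppA = dppa, HbpA2 = hbpa2)
}

#' Simulate clade-structured protein families
#'
#' Generates three (or more) clades of protein sequences diverged from a
#' single random ancestor: each clade's ancestor is the common ancestor
#' mutated at rate `inter_clade_divergence` (expected substitutions per
#' site), each member is the clade ancestor mutated at rate `divergence`,
#' and every member then receives its clade's signature residues exactly.
#' Substituted residues are drawn uniformly over the 19 alternatives (the
#' phylogeny arm only needs clade-structured divergence, not a realistic
#' substitution process). All randomness flows from `seed`.
#'
#' @param n_per_clade Sequences per clade.
#' @param seq_length Sequence length in residues (must exceed every
#'   signature position).
#' @param divergence Within-clade expected substitutions/site, in `[0, 1)`.
#' @param inter_clade_divergence Clade-ancestor divergence from the common
#'   ancestor, in `[0, 1)`.
#' @param signature_spec Named list: clade name to named character vector of
#'   position - residue (see [default_family_signatures()]).
#' @param seed Integer seed (optional).
#' @return An [aa_sequences] object named `<clade>_<i>` with a `clades`
#'   attribute (named character vector of true labels).
#' @examples
#' fam <- simulate_family_sequences(n_per_clade = 2, seed = 1)
#' attr(fam, "clades")
#' @export
simulate_family_sequences <- function(n_per_clade = 5, seq_length = 540,
                                      divergence = 0.05,
                                      inter_clade_divergence = 0.5,
                                      signature_spec = default_family_signatures(),
                                      seed = NULL) {
  .check_scalar(n_per_clade, "n_per_clade", lower = 1)
  .check_scalar(divergence, "divergence", lower = 0, upper = 1 - 1e-12)
  .check_scalar(inter_clade_divergence, "inter_clade_divergence",
                lower = 0, upper = 1 - 1e-12)
  if (!is.list(signature_spec) || is.null(names(signature_spec)))
    stop("signature_spec must be a named list of position-residue maps")
  for (cl in names(signature_spec)) {
    spec <- signature_spec[[cl]]
    pos <- as.integer(names(spec))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > seq_length))
      stop("configuration error: signature position out of range [1, ",
           seq_length, "] for clade ", cl)
    if (!all(toupper(spec) %in% AA_ALPHABET))
      stop("configuration error: non-standard signature residue for clade ",
           cl)
  }
  .with_seed(seed, {
    ancestor <- sample(AA_ALPHABET, seq_length, replace = TRUE)
    seqs <- character(0)
    clades <- character(0)
    for (cl in names(signature_spec)) {
      spec <- toupper(signature_spec[[cl]])
      pos <- as.integer(names(signature_spec[[cl]]))
      clade_anc <- .mutate_seq(ancestor, inter_clade_divergence)
      for (i in seq_len(n_per_clade)) {
        s <- .mutate_seq(clade_anc, divergence)
        s[pos] <- spec
        nm <- sprintf("%s_%d", cl, i)
        seqs[nm] <- paste0(s, collapse = "")
        clades[nm] <- cl
      }
    }
    out <- aa_sequences(seqs)
    attr(out, "clades") <- clades
    out
  })
}

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  hit <- runif(length(s)) < rate
  if (any(hit)) {
    # uniform over the 19 alternative residues
    repl <- vapply(s[hit], function(r) sample(setdiff(AA_ALPHABET, r), 1L),
                   "")
    s[hit] <- repl
  }
  s
}

#' Simulate a two-state thermofluor melt curve
#'
#' Fluorescence follows a two-state sigmoid between linear folded and
#' unfolded baselines,
#' \deqn{F(T) = (a_f + b_f T) + \frac{(a_u + b_u T) - (a_f + b_f T)}
#'   {1 + e^{(T_m - T)/w}} + \varepsilon,\quad
#'   \varepsilon \sim N(0, \sigma^2),}
#' so that at `T = Tm` the noise-free signal lies exactly midway between the
#' baselines.
#'
#' @param Tm Midpoint temperature, degrees C (must lie within the grid).
#' @param w Transition width, degrees C (> 0).
#' @param a_f,b_f Folded baseline intercept (AU) and slope (AU/degC).
#' @param a_u,b_u Unfolded baseline intercept and slope.
#' @param T_grid Temperature grid, degrees C, strictly increasing (default
#'   30-90 by 0.5, the standard scan).
#' @param noise_sd Gaussian noise standard deviation, AU (>= 0).
#' @param seed Integer seed (optional).
#' @param protein,ligand Labels for the resulting [melt_curve].
#' @return A [melt_curve].
#' @export
simulate_melt_curve <- function(Tm = 60, w = 1, a_f = 0, b_f = 0,
                                a_u = 100, b_u = 0,
                                T_grid = seq(30, 90, by = 0.5),
                                noise_sd = 0, seed = NULL,
                                protein = "", ligand = "") {
  .check_scalar(w, "w", lower = 0, strict_lower = TRUE)
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  if (any(diff(T_grid) <= 0)) stop("T_grid must be strictly increasing")
  .check_scalar(Tm, "Tm", lower = min(T_grid), upper = max(T_grid))
  fold <- a_f + b_f * T_grid
  unf <- a_u + b_u * T_grid
  f <- fold + (unf - fold) / (1 + exp((Tm - T_grid) / w))
  .with_seed(seed, {
    if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
    melt_curve(T_grid, f, protein, ligand)
  })
}

#' Simulate a one-site ITC titration
#'
#' Per-injection heats from the forward one-site perfusion model
#' ([forward_one_site()]) plus Gaussian noise, packaged with all metadata
#' needed for fitting. The default injection schedule mirrors standard
#' practice: a small initial 3 uL injection (excluded from fits by default)
#' followed by 25 injections of 10 uL.
#'
#' @param n Stoichiometry (default 1).
#' @param Kd Dissociation constant, molar.
#' @param dH Binding enthalpy, cal/mol (default -10 kcal/mol).
#' @param V0 Cell volume, litres (default 1.4 mL, a standard perfusion
#'   cell).
#' @param M0 Cell protein concentration, molar.
#' @param X0 Syringe ligand concentration, molar.
#' @param injection_volumes Litres; default `c(3e-6, rep(1e-5, 25))`.
#' @param noise_sd Gaussian noise on each heat, calories (>= 0).
#' @param temperature Kelvin (default 310.15).
#' @param seed Integer seed (optional).
#' @return A [titration_series] with attribute `truth` (the generating
#'   parameters).
#' @export
simulate_itc <- function(n = 1, Kd, dH = -1e4, V0 = 1.4e-3, M0, X0,
                         injection_volumes = c(3e-6, rep(1e-5, 25L)),
                         noise_sd = 0, temperature = 310.15, seed = NULL) {
  if (length(injection_volumes) < 5L) stop("need at least 5 injections")
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  q <- forward_one_site(n, Kd, dH, volumes = injection_volumes, V0 = V0,
                        M0 = M0, X0 = X0)
  .with_seed(seed, {
    if (noise_sd > 0) q <- q + rnorm(length(q), 0, noise_sd)
    out <- titration_series(injection_volumes, q, V0, M0, X0, temperature,
                            first_injection_excluded = TRUE)
    attr(out, "truth") <- c(n = n, Kd = Kd, dH = dH)
    out
  })
}

#' Simulate a rigid hinge-opening structure pair
#'
#' Builds a toy bilobed C-alpha structure (two Gaussian point clouds on
#' either side of a hinge point at the origin) and a second conformation in
#' which the N lobe is rigidly rotated by `angle` degrees about a random
#' axis through the hinge point while the C lobe is left untouched - the
#' geometry of a Venus-flytrap opening. Coordinates are rounded to
#' millianstrom (PDB precision) so files round-trip exactly.
#'
#' @param angle Hinge-opening angle in degrees, `0 <= angle < 180`.
#' @param n_atoms_per_lobe Number of C-alpha atoms per lobe (>= 4).
#' @param seed Integer seed (optional).
#' @return List with elements `a` and `b` ([structure_model]s), `domains`
#'   (a [domain_definition()]), `angle` and `axis`.
#' @examples
#' hp <- simulate_hinge_pair(33, seed = 1)
#' hinge_angle(hp$a, hp$b, hp$domains)
#' @export
simulate_hinge_pair <- function(angle, n_atoms_per_lobe = 20L, seed = NULL) {
  .check_scalar(angle, "angle", lower = 0, upper = 180 - 1e-9)
  n <- as.integer(n_atoms_per_lobe)
  if (n < 4L) stop("need at least 4 atoms per lobe")
  .with_seed(seed, {
    cloud <- function(center) {
      repeat {
        p <- sweep(matrix(rnorm(3 * n, sd = 3), ncol = 3), 2L, center, "+")
        sv <- svd(sweep(p, 2L, colMeans(p)), nu = 0, nv = 0)$d
        if (sv[3] > 1e-3) return(p)  # non-degenerate in all 3 directions
      }
    }
    n_lobe <- cloud(c(-10, 0, 0))
    c_lobe <- cloud(c(10, 0, 0))
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    R <- .rotation_about_axis(axis, angle * pi / 180)
    n_lobe_b <- n_lobe %*% t(R)  # hinge point is the origin
    mk <- function(nl) {
      xyz <- round(rbind(nl, c_lobe), 3)
      structure_model(data.frame(
        type = "ATOM", chain = "A", resno = seq_len(2L * n),
        resid = "ALA", elety = "CA", element = "C",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE))
    }
    list(a = mk(n_lobe), b = mk(n_lobe_b),
         domains = domain_definition(N_lobe = seq_len(n),
                                     C_lobe = n + seq_len(n)),
         angle = angle, axis = axis)
  })
}

# Rodrigues rotation matrix: angle (radians) about unit axis u.
.rotation_about_axis <- function(u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Synthetic liganded reference complex for contact extraction
#'
#' Builds a toy liganded structure whose heavy-atom contacts reproduce a
#' given signature profile exactly: a small cluster of ligand atoms sits at
#' the origin, each profile residue contributes a C-alpha placed ~3
#' angstroms from a ligand atom, and decoy residues are placed on a 12-18
#' angstrom shell, outside any plausible contact cutoff. This is a synthetic
#' stand-in for a real liganded crystal structure, used to exercise and test
#' [extract_contacts()] without external coordinates.
#'
#' @param profile A [signature_profile] (default: packaged GbpA profile).
#' @param n_decoys Number of non-contact residues to add.
#' @param ligand_id Residue name given to the ligand (default `"LIG"`).
#' @param seed Integer seed (optional).
#' @return List with `model` (a [structure_model]), `domains` (lobes split
#'   at the profile's first C-lobe position) and `ligand_id`.
#' @export
simulate_reference_complex <- function(profile = build_default_profiles()$GbpA,
                                       n_decoys = 40L, ligand_id = "LIG",
                                       seed = NULL) {
  stopifnot(inherits(profile, "signature_profile"))
  .with_seed(seed, {
    lig_xyz <- matrix(rnorm(6 * 3, sd = 1), ncol = 3)
    unit <- function(v) v / sqrt(sum(v^2))
    contact_xyz <- t(vapply(seq_len(nrow(profile)), function(k) {
      anchor <- lig_xyz[sample.int(nrow(lig_xyz), 1L), ]
      anchor + unit(rnorm(3)) * runif(1, 2.8, 3.5)
    }, numeric(3)))
    all_pos <- profile$ref_position
    decoy_pos <- setdiff(seq_len(max(all_pos) + 20L), all_pos)
    decoy_pos <- sort(sample(decoy_pos, n_decoys))
    decoy_xyz <- t(vapply(decoy_pos, function(k) {
      unit(rnorm(3)) * runif(1, 12, 18)
    }, numeric(3)))
    aa123 <- setNames(bio3d::aa.table$aa3[match(AA_ALPHABET,
                                                bio3d::aa.table$aa1)],
                      AA_ALPHABET)
    prot <- data.frame(
      type = "ATOM", chain = "A",
      resno = c(all_pos, decoy_pos),
      resid = c(aa123[profile$ref_residue], rep("ALA", length(decoy_pos))),
      elety = "CA", element = "C",
      x = c(contact_xyz[, 1], decoy_xyz[, 1]),
      y = c(contact_xyz[, 2], decoy_xyz[, 2]),
      z = c(contact_xyz[, 3], decoy_xyz[, 3]), stringsAsFactors = FALSE)
    lig <- data.frame(
      type = "HETATM", chain = "B", resno = 1L, resid = ligand_id,
      elety = sprintf("C%d", seq_len(nrow(lig_xyz))), element = "C",
      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
      stringsAsFactors = FALSE)
    at <- rbind(prot, lig)
    at[, c("x", "y", "z")] <- round(at[, c("x", "y", "z")], 3)
    first_c <- min(profile$ref_position[profile$lobe == "C"],
                   max(all_pos) + 1L)
    maxr <- max(all_pos) + 20L
    list(model = structure_model(at),
         domains = domain_definition(N_lobe = seq_len(first_c - 1L),
                                     C_lobe = first_c:maxr),
         ligand_id = ligand_id)
  })
}
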