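#' Run the family-delineation pipeline
#'
#' Orchestrates alignment, phylogeny and fingerprint classification:
#' progressive MSA of the input sequences, neighbor-joining tree with
#' Jukes-Cantor distances and column-bootstrap supports, and signature-based
#' family classification. Writes the aligned FASTA, the Newick tree (with
#' supports as internal-node labels) and the classification CSV into
#' `out_dir`. Any stage failure is re-raised with the stage name and the
#' partial outputs of this run are removed.
#'
#' @param sequences An [aa_sequences] object or path to a FASTA file
#'   (>= 3 sequences for the phylogeny stage).
#' @param out_dir Output directory (created if needed).
#' @param profiles Named list of [signature_profile]s.
#' @param ref_ids Named character vector mapping each profile to its
#'   reference sequence id; by default, for each profile the first sequence
#'   onto which the profile maps without error is used.
#' @param B Bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap resampling.
#' @param matrix A [substitution_matrix].
#' @param deletion,states Distance options, see [p_distance_matrix()] and
#'   [jc_correct()].
#' @param threshold Classification threshold, see [classify_sequences()].
#' @return Invisibly, a list with `alignment`, `tree`, `classification` and
#'   `files` (paths written).
#' @export
run_delineation <- function(sequences, out_dir,
                            profiles = build_default_profiles(),
                            ref_ids = NULL, B = 100L, seed = NULL,
                            matrix = blosum62(), deletion = "pairwise",
                            states = "aa20", threshold = 0.75) {
  if (is.character(sequences) && length(sequences) == 1L)
    sequences <- read_fasta(sequences)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("aligned.fasta", "tree.nwk",
                                "classification.csv"))
  names(files) <- c("alignment", "tree", "classification")
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[%s stage] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  aln <- stage("align", progressive_msa(sequences, matrix))
  stage("align", {
    s <- alignment_strings(aln)
    class(s) <- "aa_sequences"
    attr(s, "descriptions") <- rep("", length(s))
    write_fasta(s, files[["alignment"]])
    written <<- c(written, files[["alignment"]])
  })
  tree <- stage("phylo", bootstrap_support(aln, B = B, seed = seed,
                                           deletion = deletion,
                                           states = states))
  stage("phylo", {
    writeLines(newick_write(tree), files[["tree"]])
    written <<- c(written, files[["tree"]])
  })
  cls <- stage("fingerprint", {
    if (is.null(ref_ids)) ref_ids <- .auto_ref_ids(profiles, aln)
    classify_sequences(aln, profiles, ref_ids, threshold = threshold)
  })
  stage("fingerprint", {
    write.csv(as.data.frame(cls), files[["classification"]],
              row.names = FALSE)
    written <<- c(written, files[["classification"]])
  })
  invisible(list(alignment = aln, tree = tree, classification = cls,
                 files = files))
}

.auto_ref_ids <- function(profiles, aln) {
  vapply(names(profiles), function(f) {
    for (id in rownames(aln)) {
      ok <- tryCatch({
        map_profile_to_alignment(profiles[[f]], aln, id)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(id)
    }
    stop("no sequence in the alignment matches the '", f,
         "' profile reference residues")
  }, "")
}

#' Run the ligand-binding analysis arm
#'
#' Produces the two binding result tables: the thermofluor delta-Tm shift
#' table (from apo and holo melt-curve CSVs or [melt_curve] objects) and the
#' ITC one-site fit table (from titration CSVs or [titration_series]
#' objects). Per-input failures are collected and reported; the remaining
#' inputs are still processed.
#'
#' @param melt_apo,melt_holo Lists of [melt_curve]s or paths to melt CSVs
#'   ([read_melt_csv()] format).
#' @param itc_inputs List of [titration_series] or paths to ITC CSVs; names
#'   are used as row labels in the fit table.
#' @param out_dir Output directory.
#' @param threshold Delta-Tm significance threshold, degrees C.
#' @param ... Passed to [extract_tm()] via [build_shift_table()].
#' @return Invisibly, a list with `shift_table`, `fits` (list of
#'   [fit_one_site()] objects), `fit_table` (data frame), `errors`
#'   (character, zero-length on full success) and `files`.
#' @export
run_binding <- function(melt_apo, melt_holo = list(), itc_inputs = list(),
                        out_dir, threshold = 1.5, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  load_curve <- function(x) {
    if (inherits(x, "melt_curve")) return(x)
    read_melt_csv(x)
  }
  load_all <- function(xs) {
    out <- list()
    for (i in seq_along(xs)) {
      cv <- tryCatch(load_curve(xs[[i]]), error = function(e) {
        errors <<- c(errors, sprintf("melt input %s: %s",
                                     if (is.character(xs[[i]])) xs[[i]] else i,
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(cv)) out[[length(out) + 1L]] <- cv
    }
    out
  }
  apo <- load_all(melt_apo)
  holo <- load_all(melt_holo)
  files <- character(0)
  shift <- NULL
  if (length(apo)) {
    shift <- build_shift_table(apo, holo, threshold = threshold, ...)
    f <- file.path(out_dir, "shift_table.csv")
    write_shift_table(shift, f)
    files["shift_table"] <- f
  }
  fits <- list()
  for (i in seq_along(itc_inputs)) {
    xi <- itc_inputs[[i]]
    nm <- if (!is.null(names(itc_inputs)) && nzchar(names(itc_inputs)[i]))
      names(itc_inputs)[i] else
        if (is.character(xi)) basename(xi) else sprintf("series_%d", i)
    fit <- tryCatch({
      s <- if (inherits(xi, "titration_series")) xi else read_itc_csv(xi)
      fit_one_site(s)
    }, error = function(e) {
      errors <<- c(errors, sprintf("ITC input %s: %s", nm,
                                   conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) fits[[nm]] <- fit
  }
  fit_table <- NULL
  if (length(fits)) {
    fit_table <- do.call(rbind, lapply(names(fits), function(nm) {
      cf <- coef(fits[[nm]]); se <- fits[[nm]]$se
      data.frame(series = nm, n = cf[["n"]], n_se = se[["n"]],
                 Kd_uM = cf[["Kd"]] * 1e6, Kd_se_uM = se[["Kd"]] * 1e6,
                 dH_kcal = cf[["dH"]] / 1e3, dH_se_kcal = se[["dH"]] / 1e3,
                 residual_sd = fits[[nm]]$sigma,
                 lack_of_fit = fits[[nm]]$lack_of_fit,
                 stringsAsFactors = FALSE)
    }))
    f <- file.path(out_dir, "binding_fits.csv")
    write.csv(fit_table, f, row.names = FALSE)
    files["binding_fits"] <- f
  }
  if (length(errors))
    warning("run_binding: ", length(errors), " input(s) failed:\n  ",
            paste(errors, collapse = "\n  "))
  invisible(list(shift_table = shift, fits = fits, fit_table = fit_table,
                 errors = errors, files = files))
}

#' Write a complete synthetic demo dataset
#'
#' Populates a directory with a synthetic dataset exercising every arm of
#' the pipeline: a three-clade FASTA family, replicate apo/holo melt-curve
#' CSVs for a small protein-by-ligand panel, one-site ITC titration CSVs,
#' and a hinge-opening PDB pair, plus a `config.dcf` recording the seed and
#' generating parameters.
#'
#' @param dir Target directory (created).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return Invisibly, a list of the paths written, grouped by arm.
#' @export
make_demo <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  fam <- simulate_family_sequences(n_per_clade = 5, seed = seed)
  fasta <- file.path(dir, "family.fasta")
  write_fasta(fam, fasta)
  writeLines(paste(names(attr(fam, "clades")), attr(fam, "clades"),
                   sep = ","),
             file.path(dir, "true_clades.csv"))

  proteins <- c("GbpA_Hi", "GbpA_Ap", "GbpA_Hp", "GbpA_Pm", "HbpA2_Hp")
  ligands <- c("GSSG", "GSH")
  shifts <- rbind(GSSG = c(17.5, 14.0, 16.0, 20.5, 0),
                  GSH = c(12.5, 11.0, 14.0, 13.0, 0))
  colnames(shifts) <- proteins
  melt_files <- character(0)
  k <- 0L
  for (p in proteins) for (lg in c("", ligands)) for (rep_i in 1:2) {
    k <- k + 1L
    tm <- 60 + if (nzchar(lg)) shifts[lg, p] else 0
    cv <- simulate_melt_curve(Tm = tm, noise_sd = 2, seed = seed + 1000L + k,
                              protein = p, ligand = lg)
    f <- file.path(dir, sprintf("melt_%02d_%s_%s.csv", k, p,
                                if (nzchar(lg)) lg else "apo"))
    write_melt_csv(cv, f)
    melt_files <- c(melt_files, f)
  }

  kd <- c(GbpA_Hi_GSSG = 12.9e-6, GbpA_Ap_GSSG = 0.33e-6,
          GbpA_Hp_GSSG = 2.1e-6, GbpA_Pm_GSSG = 0.15e-6)
  itc_files <- character(0)
  for (i in seq_along(kd)) {
    M0 <- 50 * kd[[i]]  # keep the Wiseman c-value at 50
    q0 <- forward_one_site(1, kd[[i]], -1e4, volumes = c(3e-6, rep(1e-5, 25)),
                           V0 = 1.4e-3, M0 = M0, X0 = 12 * M0)
    s <- simulate_itc(Kd = kd[[i]], M0 = M0, X0 = 12 * M0,
                      noise_sd = 0.01 * max(abs(q0)),
                      seed = seed + 2000L + i)
    f <- file.path(dir, sprintf("itc_%s.csv", names(kd)[i]))
    write_itc_csv(s, f)
    itc_files <- c(itc_files, f)
  }

  hp <- simulate_hinge_pair(33, seed = seed + 3000L)
  pdb_files <- file.path(dir, c("closed_conformer.pdb",
                                "open_conformer.pdb"))
  write_structure(hp$a, pdb_files[1])
  write_structure(hp$b, pdb_files[2])

  write.dcf(data.frame(seed = seed, n_per_clade = 5, seq_length = 540,
                       melt_noise_sd = 2, itc_noise = "1% of max heat",
                       hinge_angle_deg = 33),
            file.path(dir, "config.dcf"))
  invisible(list(fasta = fasta, melt = melt_files, itc = itc_files,
                 pdb = pdb_files,
                 config = file.path(dir, "config.dcf")))
}
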