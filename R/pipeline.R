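#' Run the full trajectory-analysis pipeline over replicates
#'
#' Orchestrates every stage — activation-state classification, interaction
#' energy with per-residue decomposition, loop RMSF, contact census, and
#' center-of-mass distance series — over one or more replicate
#' trajectories sharing a topology, and aggregates them: active fractions
#' are pooled frame-weighted, energies report both per-frame standard
#' deviation and the spread across replicate means, RMSF sums and census
#' counts are given per replicate and averaged. A stage failure is
#' recorded under `errors` with its stage name while the remaining stages
#' still run.
#'
#' @param replicates One `md_trajectory` or a list of them.
#' @param topology Shared `md_topology`.
#' @param criteria An [activation_criteria()].
#' @param energy_config A [nonbonded_config()].
#' @param loop_residues Residue numbers of the flexible loop (e.g. ECL2)
#'   whose Calpha RMSF is summed; `NULL` skips the RMSF stage.
#' @param com_pairs Named list of residue pairs for COM distances, each
#'   `list(a = <residue selector>, b = <residue selector>)` (see
#'   [com_distance_series()]); `NULL` skips the stage.
#' @param contact_cutoff Contact cutoff in angstrom (default 3.0).
#' @param occupancy_threshold Census membership threshold (default 0.5).
#' @param class_table Side-chain class table.
#' @param stride Frame stride applied to every stage.
#' @param seed Seed recorded in provenance (the pipeline itself draws no
#'   random numbers).
#' @return Object of class `md_report`: a list of stage tibbles plus
#'   provenance.
#' @export
run_pipeline <- function(replicates, topology, criteria,
                         energy_config = nonbonded_config(),
                         loop_residues = NULL, com_pairs = NULL,
                         contact_cutoff = 3.0, occupancy_threshold = 0.5,
                         class_table = default_class_table(),
                         stride = 1, seed = NULL) {
  if (inherits(replicates, "md_trajectory")) replicates <- list(replicates)
  nrep <- length(replicates)
  errors <- list()
  note_error <- function(stage, e) {
    errors[[length(errors) + 1]] <<- tibble(stage = stage,
                                            message = conditionMessage(e))
    NULL
  }
  per_stage <- function(stage, fn) {
    lapply(seq_len(nrep), function(r) {
      tryCatch(fn(replicates[[r]], r), error = function(e) note_error(
        paste0(stage, " (replicate ", r, ")"), e))
    })
  }

  act <- per_stage("activation", function(tr, r) {
    g <- glance(active_fraction(tr, topology, criteria, stride))
    mutate(g, replicate = r, .before = 1)
  })
  act_tbl <- bind_rows(act)
  act_pooled <- if (nrow(act_tbl) > 0) {
    pooled_fraction(act_tbl$fraction, act_tbl$n_frames)
  } else {
    NULL
  }

  en <- per_stage("energy", function(tr, r)
    trajectory_energy_series(tr, topology, energy_config, stride))
  en_ok <- !vapply(en, is.null, logical(1))
  en_tbl <- bind_rows(lapply(which(en_ok), function(r)
    mutate(glance(en[[r]]), replicate = r, .before = 1)))
  en_summary <- if (any(en_ok)) {
    m <- en_tbl
    tibble(
      total_mean = sum(m$total_mean * m$n_frames) / sum(m$n_frames),
      coulomb_mean = sum(m$coulomb_mean * m$n_frames) / sum(m$n_frames),
      lj_mean = sum(m$lj_mean * m$n_frames) / sum(m$n_frames),
      # two uncertainty conventions, neither canonical: the mean per-frame
      # sd within replicates, and the sd across replicate means
      total_sd_frames = mean(m$total_sd),
      total_sd_replicates = if (nrow(m) > 1) sd(m$total_mean) else NA_real_,
      n_replicates = nrow(m), n_frames = sum(m$n_frames)
    )
  } else {
    NULL
  }
  en_residue <- if (any(en_ok)) {
    bind_rows(lapply(which(en_ok), function(r) tidy(en[[r]], "residue"))) |>
      group_by(.data$chain_id, .data$residue_index, .data$residue_name) |>
      summarise(coulomb = mean(.data$coulomb), lj = mean(.data$lj),
                total = mean(.data$total), .groups = "drop")
  } else {
    NULL
  }

  rm_tbl <- rm_residue <- NULL
  if (!is.null(loop_residues)) {
    rm <- per_stage("rmsf", function(tr, r) {
      sel <- select_atoms(topology, residues = loop_residues,
                          atom_names = "CA", group = "receptor")
      rmsf(tr, topology, sel, stride = stride)
    })
    rm_ok <- !vapply(rm, is.null, logical(1))
    rm_tbl <- bind_rows(lapply(which(rm_ok), function(r)
      mutate(glance(rm[[r]]), replicate = r, .before = 1)))
    if (any(rm_ok)) {
      rm_residue <- bind_rows(lapply(which(rm_ok), function(r) tidy(rm[[r]]))) |>
        group_by(.data$chain_id, .data$residue_index, .data$residue_name) |>
        summarise(rmsf = mean(.data$rmsf), .groups = "drop")
    }
  }

  ct <- per_stage("contacts", function(tr, r)
    contact_census(tr, topology, cutoff = contact_cutoff,
                   class_table = class_table,
                   occupancy_threshold = occupancy_threshold,
                   stride = stride))
  ct_ok <- !vapply(ct, is.null, logical(1))
  ct_tbl <- bind_rows(lapply(which(ct_ok), function(r)
    mutate(glance(ct[[r]]), replicate = r, .before = 1)))
  ct_residue <- if (any(ct_ok)) {
    bind_rows(lapply(which(ct_ok), function(r) tidy(ct[[r]]))) |>
      group_by(.data$chain_id, .data$residue_index, .data$residue_name,
               .data$class) |>
      summarise(occupancy = mean(.data$occupancy), .groups = "drop")
  } else {
    NULL
  }

  com_tbl <- NULL
  if (!is.null(com_pairs)) {
    com_rows <- list()
    for (pn in names(com_pairs)) {
      p <- com_pairs[[pn]]
      for (r in seq_len(nrep)) {
        res <- tryCatch(
          com_distance_series(replicates[[r]], topology, p$a, p$b, stride),
          error = function(e) note_error(paste0("com (", pn, ", replicate ",
                                                r, ")"), e))
        if (!is.null(res)) {
          com_rows[[length(com_rows) + 1]] <- tibble(
            pair = pn, replicate = r,
            mean_distance = attr(res, "mean_distance"),
            n_frames = nrow(res))
        }
      }
    }
    com_tbl <- bind_rows(com_rows)
  }

  provenance <- list(
    package = "gpcrmd",
    version = as.character(utils::packageVersion("gpcrmd")),
    seed = seed,
    stride = stride,
    discard_before_ps = vapply(replicates, function(tr) tr$discard_before,
                               numeric(1)),
    cutoff_angstrom = energy_config$cutoff,
    contact_cutoff_angstrom = contact_cutoff,
    occupancy_threshold = occupancy_threshold,
    n_replicates = nrep
  )
  provenance$config_hash <- rlang::hash(provenance)

  structure(list(
    activation = list(per_replicate = act_tbl, pooled = act_pooled),
    energy = list(per_replicate = en_tbl, summary = en_summary,
                  per_residue = en_residue),
    rmsf = list(per_replicate = rm_tbl, per_residue = rm_residue),
    contacts = list(per_replicate = ct_tbl, per_residue = ct_residue),
    com = com_tbl,
    errors = if (length(errors) > 0) bind_rows(errors)
             else tibble(stage = character(), message = character()),
    provenance = provenance
  ), class = "md_report")
}

#' @export
print.md_report <- function(x, ...) {
  cat("<md_report> ", x$provenance$n_replicates, " replicate(s)\n", sep = "")
  if (!is.null(x$activation$pooled)) {
    cat(sprintf("  active fraction (pooled): %.4f\n", x$activation$pooled$pooled))
  }
  if (!is.null(x$energy$summary)) {
    s <- x$energy$summary
    cat(sprintf("  interaction energy: %.2f kJ/mol (coulomb %.2f, LJ %.2f)\n",
                s$total_mean, s$coulomb_mean, s$lj_mean))
  }
  if (!is.null(x$rmsf$per_replicate) && nrow(x$rmsf$per_replicate) > 0) {
    cat(sprintf("  loop RMSF sum (mean over replicates): %.3f A\n",
                mean(x$rmsf$per_replicate$selection_sum)))
  }
  if (nrow(x$errors) > 0) {
    cat("  stage errors: ", paste(x$errors$stage, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (the full report), TSV tables per stage and a
#' human-readable `summary.md` into `dir`. Output is byte-deterministic
#' for identical reports (no timestamps).
#'
#' @param report An `md_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  unclass_tibbles <- function(x) {
    if (is.data.frame(x)) as.data.frame(x)
    else if (is.list(x)) lapply(x, unclass_tibbles)
    else x
  }
  jsonlite::write_json(unclass_tibbles(unclass(report)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  prov <- report$provenance[c("seed", "stride", "config_hash")]
  tables <- list(
    activation = report$activation$per_replicate,
    energy = report$energy$per_replicate,
    energy_residue = report$energy$per_residue,
    rmsf = report$rmsf$per_replicate,
    rmsf_residue = report$rmsf$per_residue,
    contacts = report$contacts$per_replicate,
    contacts_residue = report$contacts$per_residue,
    com = report$com
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]) && nrow(tables[[nm]]) > 0) {
      write_results(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                    format = "tsv", provenance = prov)
    }
  }
  md <- c("# Trajectory analysis report", "")
  if (!is.null(report$activation$pooled)) {
    md <- c(md, sprintf("- Active fraction (pooled, frame-weighted): %.4f",
                        report$activation$pooled$pooled))
  }
  if (!is.null(report$energy$summary)) {
    s <- report$energy$summary
    md <- c(md, sprintf("- Interaction energy: %.2f kJ/mol (Coulomb %.2f, LJ %.2f)",
                        s$total_mean, s$coulomb_mean, s$lj_mean))
  }
  if (!is.null(report$rmsf$per_replicate) && nrow(report$rmsf$per_replicate) > 0) {
    md <- c(md, sprintf("- Loop RMSF sum per replicate: %s A",
                        paste(sprintf("%.3f", report$rmsf$per_replicate$selection_sum),
                              collapse = ", ")))
  }
  if (!is.null(report$contacts$per_replicate) && nrow(report$contacts$per_replicate) > 0) {
    md <- c(md, sprintf("- Contact census size per replicate: %s",
                        paste(report$contacts$per_replicate$n_census,
                              collapse = ", ")))
  }
  if (nrow(report$errors) > 0) {
    md <- c(md, "", "## Stage errors",
            paste0("- ", report$errors$stage, ": ", report$errors$message))
  }
  md <- c(md, "", paste0("config hash: ", report$provenance$config_hash))
  con <- file(file.path(dir, "summary.md"), open = "wb")
  writeLines(md, con)
  close(con)
  invisible(dir)
}

#' Compare two analysis reports
#'
#' Signed difference and percent change for the headline quantities of two
#' systems. Convention: `delta = b - a` and
#' `pct_change = 100 * (b - a) / |a|`, so positive means larger in system
#' B. Quantities missing from either report yield an `NA` row rather than
#' a failure.
#'
#' @param report_a,report_b `md_report` objects.
#' @return Tibble with `quantity`, `a`, `b`, `delta`, `pct_change`.
#' @export
compare_systems <- function(report_a, report_b) {
  pull_quantities <- function(rep) {
    out <- c(active_fraction = NA_real_, total_energy = NA_real_,
             coulomb_energy = NA_real_, lj_energy = NA_real_,
             rmsf_sum = NA_real_, n_contacts = NA_real_,
             n_hydrophobic = NA_real_, n_charged = NA_real_,
             n_polar_uncharged = NA_real_)
    if (!is.null(rep$activation$pooled)) {
      out["active_fraction"] <- rep$activation$pooled$pooled
    }
    if (!is.null(rep$energy$summary)) {
      out["total_energy"] <- rep$energy$summary$total_mean
      out["coulomb_energy"] <- rep$energy$summary$coulomb_mean
      out["lj_energy"] <- rep$energy$summary$lj_mean
    }
    if (!is.null(rep$rmsf$per_replicate) && nrow(rep$rmsf$per_replicate) > 0) {
      out["rmsf_sum"] <- mean(rep$rmsf$per_replicate$selection_sum)
    }
    ct <- rep$contacts$per_replicate
    if (!is.null(ct) && nrow(ct) > 0) {
      out["n_contacts"] <- mean(ct$n_census)
      for (cl in c("hydrophobic", "charged", "polar_uncharged")) {
        col <- paste0("n_", cl)
        if (col %in% names(ct)) out[col] <- mean(ct[[col]])
      }
    }
    out
  }
  qa <- pull_quantities(report_a)
  qb <- pull_quantities(report_b)
  qa <- unname(qa)
  qb <- unname(qb)
  tibble(
    quantity = c("active_fraction", "total_energy", "coulomb_energy",
                 "lj_energy", "rmsf_sum", "n_contacts", "n_hydrophobic",
                 "n_charged", "n_polar_uncharged"),
    a = qa, b = qb, delta = qb - qa,
    pct_change = ifelse(is.na(qa) | qa == 0, NA_real_,
                        100 * (qb - qa) / abs(qa))
  )
}
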