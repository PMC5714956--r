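# Orchestration of the four analysis stages. Each stage returns a report
# list and (when `out_dir` is given) writes machine-readable TSV/JSON
# artifacts plus a run manifest sufficient to re-run deterministically.

write_manifest <- function(out_dir, stage, params) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("confsel")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   parameters = params)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, file.path(out_dir, name), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Stage: free-peptide secondary structure
#'
#' Secondary shifts, SSP profile, per-region mean SSP (the helix-population
#' summary), optional 3J-based populations, and the CSI consensus string.
#'
#' @param shifts free-state shift table.
#' @param j optional coupling table (resno, resname, value).
#' @param regions named list of residue ranges summarized (defaults: the
#'   two helices of the packaged peptide spec).
#' @param window SSP window.
#' @param rc random-coil table.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list(secondary, ssp, region_summary, csi, j_populations).
#' @export
stage_free_peptide <- function(shifts, j = NULL,
                               regions = list(helix1 = c(786, 790),
                                              helix2 = c(799, 808)),
                               window = 5L, rc = random_coil_table(),
                               out_dir = NULL) {
  sec <- secondary_shifts(shifts, rc)
  prof <- ssp(shifts, rc, window = window)
  region_summary <- do.call(rbind, lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    inr <- prof$resno >= r[1] & prof$resno <= r[2]
    data.frame(region = nm, start = r[1], end = r[2],
               mean_ssp = mean(prof$score[inr]), n = sum(inr))
  }))
  cs <- csi(shifts, rc)
  jp <- if (!is.null(j)) helix_population_from_J(j, rc = rc) else NULL
  if (!is.null(jp) && !is.null(region_summary)) {
    region_summary$mean_J_population <- vapply(seq_len(nrow(region_summary)),
      function(k) {
        inr <- jp$resno >= region_summary$start[k] &
          jp$resno <= region_summary$end[k]
        if (any(inr)) mean(jp$population[inr]) else NA_real_
      }, numeric(1))
  }
  write_tsv(sec, out_dir, "secondary_shifts.tsv")
  write_tsv(as.data.frame(prof), out_dir, "ssp_profile.tsv")
  write_tsv(region_summary, out_dir, "region_summary.tsv")
  write_manifest(out_dir, "free_peptide",
                 list(window = window, regions = regions))
  list(secondary = sec, ssp = prof, region_summary = region_summary,
       csi = cs, j_populations = jp)
}

#' Stage: chemical shift perturbation mapping
#'
#' CSP table per the weighted-average formula, its mean (the reference line
#' for calling perturbed residues) and the list of residues above the mean.
#'
#' @param free,bound shift tables of the two states.
#' @param intensity_ratio optional (resno, ratio) table of I_bound/I_free.
#' @param out_dir optional output directory.
#' @return list(csp, mean_csp, above_mean).
#' @export
stage_csp <- function(free, bound, intensity_ratio = NULL, out_dir = NULL) {
  tab <- csp(free, bound, intensity_ratio = intensity_ratio)
  m <- attr(tab, "mean_csp")
  above <- tab$resno[tab$delta_obs > m]
  write_tsv(tab, out_dir, "csp.tsv")
  write_manifest(out_dir, "csp", list(mean_csp = m, above_mean = above,
                                      excluded = attr(tab, "excluded")))
  list(csp = tab, mean_csp = m, above_mean = above)
}

#' Stage: RDC validation of a structure
#'
#' Alignment-tensor fit on the stated residues, back-calculation for all
#' residues, Q factor and Pearson r, plus the measured-vs-calculated pairs
#' for a correlation plot.
#'
#' @param s an `nmr_structure`.
#' @param rdcs RDC table.
#' @param fit_residues residues entering the fit (e.g. secondary-structure
#'   residues); default all.
#' @param eval_residues residues entering Q/r; default the fitted set.
#' @param model model index.
#' @param chain chain identifier.
#' @param out_dir optional output directory.
#' @return list(fit (`rdc_fit`), correlation = data.frame(resno, d_exp,
#'   d_calc)).
#' @export
stage_rdc_validation <- function(s, rdcs, fit_residues = NULL,
                                 eval_residues = NULL, model = 1L,
                                 chain = NULL, out_dir = NULL) {
  fit <- fit_tensor_svd(s, model, rdcs, residues_used = fit_residues,
                        eval_residues = eval_residues, chain = chain)
  common <- intersect(names(fit$d_calc), names(fit$d_exp))
  corr <- data.frame(resno = as.integer(common),
                     d_exp = unname(fit$d_exp[common]),
                     d_calc = unname(fit$d_calc[common]))
  write_tsv(corr, out_dir, "rdc_correlation.tsv")
  if (!is.null(out_dir)) {
    jsonlite::write_json(rdc_fit_report(fit),
                         file.path(out_dir, "rdc_fit.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  write_manifest(out_dir, "rdc_validation",
                 list(model = model, fit_residues = fit$residues_used,
                      q = fit$q, pearson_r = fit$pearson_r))
  list(fit = fit, correlation = corr)
}

#' Stage: tertiary preorganization test
#'
#' Runs the full RDC-based test of whether the free peptide's two helices
#' already adopt their bound-form arrangement:
#' (a) independent peptide and domain fits of the bound-state couplings,
#'     with the NSP between the two tensors and the cross-fit Q (peptide
#'     couplings predicted under the domain tensor);
#' (b) fit of the free-form couplings to the bound peptide structure, both
#'     unscaled and with an optimal overall scale;
#' (c) rotated control models SM1-SM4 (the first helix turned by
#'     `rotate_deg` about each of the four perpendicular axes) fitted
#'     against the free couplings;
#' (d) sample -> cluster -> angle-filter -> per-conformer Q over a sampled
#'     ensemble.
#' Sub-stages are skipped when their inputs are `NULL`.
#'
#' @param peptide_structure single-model `nmr_structure` of the bound-form
#'   peptide.
#' @param free_rdcs free-state peptide couplings.
#' @param bound_rdcs_peptide,bound_rdcs_domain bound-state couplings of the
#'   peptide and of the domain (optional).
#' @param domain_structure structure carrying the domain coordinates
#'   (optional; may equal `peptide_structure` with another chain).
#' @param domain_chain,peptide_chain chain identifiers.
#' @param helix1,helix2 helix ranges (author numbering).
#' @param linker linker range perturbed by the sampler.
#' @param theta_ref reference interhelical angle; default: computed from
#'   `peptide_structure`.
#' @param half_window exclusion half-width for [filter_by_angle()].
#' @param rotate_deg rotation of the SM1-SM4 controls (degrees).
#' @param n_conformers ensemble size for sub-stage (d).
#' @param rng_seed sampler seed.
#' @param fit_residues_peptide residues used in the peptide fits.
#' @param out_dir optional output directory.
#' @return list(bound_fits, free_fit, rotated_models, ensemble, summary)
#'   where `summary` is a flat table of all Q factors.
#' @export
stage_preorganization <- function(peptide_structure, free_rdcs,
                                  bound_rdcs_peptide = NULL,
                                  bound_rdcs_domain = NULL,
                                  domain_structure = NULL,
                                  domain_chain = NULL, peptide_chain = NULL,
                                  helix1 = c(786, 790), helix2 = c(799, 808),
                                  linker = c(791, 798),
                                  theta_ref = NULL, half_window = 30,
                                  rotate_deg = 30,
                                  n_conformers = 500L, rng_seed = 1L,
                                  fit_residues_peptide = NULL,
                                  out_dir = NULL) {
  s <- peptide_structure
  if (is.null(peptide_chain)) peptide_chain <- s$atoms$chain[1]
  h1 <- fit_helix_axis(s, 1, peptide_chain, helix1[1], helix1[2])
  h2 <- fit_helix_axis(s, 1, peptide_chain, helix2[1], helix2[2])
  if (is.null(theta_ref)) theta_ref <- interhelical_angle(h1, h2)
  summary_rows <- list()
  note <- function(label, q, extra = NA_real_) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(quantity = label, value = q, theta = extra)
  }

  # (a) bound-state peptide/domain fits, NSP, cross Q
  bound_fits <- NULL
  if (!is.null(bound_rdcs_peptide)) {
    fit_pep <- fit_tensor_svd(s, 1, bound_rdcs_peptide,
                              residues_used = fit_residues_peptide,
                              chain = peptide_chain)
    note("Q_peptide_bound", fit_pep$q)
    bound_fits <- list(peptide = fit_pep)
    if (!is.null(bound_rdcs_domain) && !is.null(domain_structure)) {
      fit_dom <- fit_tensor_svd(domain_structure, 1, bound_rdcs_domain,
                                chain = domain_chain)
      note("Q_domain_bound", fit_dom$q)
      note("NSP_peptide_domain", nsp(fit_pep$tensor, fit_dom$tensor))
      # cross fit: peptide couplings under the domain tensor
      vpep <- nh_vectors(s, 1, chain = peptide_chain)
      dpred <- predict_rdc(vpep, fit_dom$tensor)
      common <- intersect(vpep$resno, bound_rdcs_peptide$resno)
      qx <- q_factor(bound_rdcs_peptide$d_exp[match(common, bound_rdcs_peptide$resno)],
                     dpred[as.character(common)])
      note("Q_cross_peptide_under_domain_tensor", qx)
      bound_fits$domain <- fit_dom
      bound_fits$cross_q <- qx
    }
  }

  # (b) free couplings against the bound structure, unscaled + scaled
  free_fit <- fit_tensor_svd(s, 1, free_rdcs,
                             residues_used = fit_residues_peptide,
                             chain = peptide_chain)
  note("Q_free_on_bound_structure", free_fit$q, theta_ref)
  ev <- free_fit$eval_residues
  de <- free_fit$d_exp[as.character(ev)]
  dc <- free_fit$d_calc[as.character(ev)]
  scale_opt <- sum(de * dc) / sum(dc^2)
  note("Q_free_on_bound_structure_scaled", q_factor(de, scale_opt * dc),
       theta_ref)

  # (c) rotated models SM1-SM4
  rotated <- lapply(1:4, function(ax) {
    sr <- rotate_segment(s, h1, h2, rotate_deg, axis_index = ax)
    th <- interhelical_angle(
      fit_helix_axis(sr, 1, peptide_chain, helix1[1], helix1[2]),
      fit_helix_axis(sr, 1, peptide_chain, helix2[1], helix2[2]))
    fit <- fit_tensor_svd(sr, 1, free_rdcs,
                          residues_used = fit_residues_peptide,
                          chain = peptide_chain)
    note(sprintf("Q_free_on_rotated_SM%d", ax), fit$q, th)
    list(structure = sr, theta = th, fit = fit)
  })

  # (d) ensemble: sample, cluster, angle-filter, per-conformer Q
  ens_result <- NULL
  if (n_conformers > 0) {
    rr <- range(s$atoms$resno[s$atoms$chain == peptide_chain])
    perturb <- c(seq(rr[1], helix1[1] - 1L),
                 seq(linker[1], linker[2]),
                 seq(helix2[2] + 1L, rr[2]))
    ens <- sample_conformers(s, n_conformers, rng_seed, perturb,
                             helix1 = helix1, helix2 = helix2,
                             chain = peptide_chain)
    ens <- cluster_ensemble(ens, chain = peptide_chain)
    reps <- ensemble_subset(ens, ens$meta$representative)
    filt <- filter_by_angle(reps, theta_ref, half_window)
    if (nrow(filt$meta) > 0) {
      evq <- evaluate_ensemble_q(filt, free_rdcs,
                                 fit_residues = fit_residues_peptide,
                                 chain = peptide_chain)
      note("Q_ensemble_min", min(evq$report$q_free),
           evq$report$theta_deg[1])
      ens_result <- list(ensemble = ens, filtered = evq$ensemble,
                         report = evq$report)
    } else {
      ens_result <- list(ensemble = ens, filtered = filt, report = NULL)
    }
  }

  summary <- do.call(rbind, summary_rows)
  write_tsv(summary, out_dir, "preorganization_summary.tsv")
  if (!is.null(ens_result$report)) {
    write_tsv(ens_result$report, out_dir, "ensemble_q.tsv")
  }
  write_manifest(out_dir, "preorganization",
                 list(theta_ref = theta_ref, half_window = half_window,
                      rotate_deg = rotate_deg, n_conformers = n_conformers,
                      rng_seed = rng_seed))
  list(bound_fits = bound_fits, free_fit = free_fit,
       rotated_models = rotated, ensemble = ens_result, summary = summary)
}
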