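# End-to-end orchestration: preprocessing, balanced epoching, spectral /
# connectivity / network measures for the three unit systems -- hdEEG(ROI)
# (source-reconstructed scalp), iEEG(channel) (bipolar depth channels) and
# iEEG(ROI) (channel measures aggregated to atlas regions) -- followed by
# group-level statistics.

# One-pass computation of the three band measures (power, ITC, wPLI) from
# a single set of trial FFTs.
band_measures <- function(epochs, band) {
  if (is.data.frame(band)) band <- as.list(band[1, ])
  d <- dim(epochs$trials)
  bins <- band_bins(d[3], epochs$fs, band)
  Xb <- trial_fft(epochs)[, , bins, drop = FALSE]
  norm <- epochs$fs * taper_energy(epochs)
  psd <- vapply(seq_len(d[2]), function(c) {
    mean(2 * Mod(Xb[, c, , drop = FALSE])^2 / norm)
  }, numeric(1))
  names(psd) <- epochs$channel_labels
  itcv <- vapply(seq_len(d[2]), function(c) {
    Z <- Xb[, c, , drop = FALSE]
    m <- Mod(Z); m[m == 0] <- 1
    mean(Mod(apply(Z / m, c(2, 3), mean)))
  }, numeric(1))
  names(itcv) <- epochs$channel_labels
  xs <- structure(list(X = Xb, freqs = (bins - 1L) * epochs$fs / d[3],
                       band = band, labels = epochs$channel_labels),
                  class = "cross_spectra")
  list(psd = psd, itc = itcv, W = wpli(xs))
}

# ERSP and ITC maps for both conditions from one wavelet pass per
# condition, with the control-condition mean power as the shared baseline.
tf_pair_maps <- function(hip_ied, hip_no, freqs) {
  acc_no <- tf_accumulate(hip_no, freqs)
  acc_ied <- tf_accumulate(hip_ied, freqs)
  bl <- rowMeans(acc_no$mean_power)
  mk <- function(acc, ep, kind) {
    vals <- if (kind == "ersp") {
      10 * log10(sweep(acc$mean_power, 1L, bl, `/`))
    } else Mod(acc$mean_phasor)
    new_tfmap(vals, freqs, tf_times(ep), acc$coi_hw, kind)
  }
  list(ersp_IED = mk(acc_ied, hip_ied, "ersp"),
       ersp_no_IED = mk(acc_no, hip_no, "ersp"),
       itc_IED = mk(acc_ied, hip_ied, "itc"),
       itc_no_IED = mk(acc_no, hip_no, "itc"))
}

balanced_epochs <- function(rec, events, extractor, seed) {
  full <- lapply(c("IED", "no_IED"), function(cond) extractor(cond, NULL))
  n_keep <- min(vapply(full, n_trials, integer(1)))
  names(full) <- c("IED", "no_IED")
  for (cond in names(full)) {
    if (n_trials(full[[cond]]) > n_keep) {
      full[[cond]] <- extractor(cond, n_keep)
    }
  }
  full
}

#' Analyze one patient
#'
#' Runs the per-patient stages: preprocessing of both modalities, balanced
#' condition epoching, hippocampal time-frequency maps (ERSP/ITC with a
#' common control-condition baseline), band power/ITC, wPLI connectivity
#' and network metrics for iEEG(channel), iEEG(ROI) and hdEEG(ROI), and
#' discharge rates with the irritative-zone rule.
#'
#' @param patient A [generate_patient()]-shaped list (`ieeg`, `scalp`,
#'   `events`, `channel_map`, `mixing`, `source_rois`, `truth`).
#' @param bands Band table (default [band_specs()]).
#' @param modalities Subset of `c("ieeg", "hdeeg")` to analyze.
#' @param freqs Wavelet frequency axis for the TF maps.
#' @param balance_seed Seed for the equal-count epoch subsampling.
#' @return List of per-patient tables and maps (see [run_pipeline()]).
#' @export
analyze_patient <- function(patient, bands = band_specs(),
                            modalities = c("ieeg", "hdeeg"),
                            freqs = morse_freqs(), balance_seed = 1L) {
  ied_roi <- attr(patient$truth, "ied_roi")
  events <- patient$events
  out <- list(patient_index = patient$patient_index,
              band_rows = list(), net_rows = list(), nodal_rows = list(),
              tfmaps = list(), conn = list())

  analyze_modality <- function(rec, mod, roi_map, roi_agg) {
    # TF maps of the discharge region's unit
    hip_unit <- if (mod == "hdeeg") ied_roi else
      roi_map$channel_label[match(ied_roi, roi_map$roi)]
    tfm <- NULL
    if (!is.na(hip_unit) && hip_unit %in% rec$labels) {
      tf <- balanced_epochs(rec, events, function(cond, nk) {
        extract_tf_epochs(rec, events, cond, nk, balance_seed)
      }, balance_seed)
      hip <- lapply(tf, epochs_channel, channel = hip_unit)
      tfm <- c(tf_pair_maps(hip$IED, hip$no_IED, freqs), unit = hip_unit)
    }
    band_rows <- list(); net_rows <- list(); nodal_rows <- list()
    conn <- list()
    for (bi in seq_len(nrow(bands))) {
      b <- as.list(bands[bi, ])
      win <- build_window(b, rec$fs)
      eps <- balanced_epochs(rec, events, function(cond, nk) {
        extract_epochs(rec, events, win, cond, nk, balance_seed)
      }, balance_seed)
      for (cond in names(eps)) {
        bm <- band_measures(eps[[cond]], b)
        psd <- bm$psd; itcv <- bm$itc; W <- bm$W
        units <- list(channel = list(psd = psd, itc = itcv, W = W))
        if (roi_agg) {
          units$roi <- list(psd = aggregate_units_to_roi(psd, roi_map),
                            itc = aggregate_units_to_roi(itcv, roi_map),
                            W = aggregate_pairs_to_roi(W, roi_map))
        }
        for (lvl in names(units)) {
          u <- units[[lvl]]
          mod_lvl <- if (mod == "hdeeg") "hdEEG(ROI)" else
            if (lvl == "roi") "iEEG(ROI)" else "iEEG(channel)"
          nm <- network_metrics(u$W)
          band_rows[[length(band_rows) + 1L]] <- data.frame(
            modality = mod_lvl, unit = names(u$psd), band = b$name,
            condition = cond,
            power = as.numeric(u$psd), itc = as.numeric(u$itc),
            stringsAsFactors = FALSE)
          nodal_rows[[length(nodal_rows) + 1L]] <- data.frame(
            modality = mod_lvl, unit = nm$unit_labels, band = b$name,
            condition = cond, clustering = as.numeric(nm$clustering),
            nodal_efficiency = as.numeric(nm$nodal_efficiency),
            stringsAsFactors = FALSE)
          net_rows[[length(net_rows) + 1L]] <- data.frame(
            modality = mod_lvl, band = b$name, condition = cond,
            segregation = nm$mean_clustering,
            integration = nm$global_efficiency, stringsAsFactors = FALSE)
          conn[[mod_lvl]][[b$name]][[cond]] <- u$W
        }
      }
    }
    list(tfm = tfm, band_rows = band_rows, net_rows = net_rows,
         nodal_rows = nodal_rows, conn = conn)
  }

  if ("ieeg" %in% modalities) {
    ie <- preprocess(patient$ieeg)
    roi_map <- data.frame(channel_label = ie$labels,
                          roi = ie$annotations$roi, stringsAsFactors = FALSE)
    res <- analyze_modality(ie, "ieeg", roi_map, roi_agg = TRUE)
    out$tfmaps$ieeg <- res$tfm
    out$band_rows <- c(out$band_rows, res$band_rows)
    out$net_rows <- c(out$net_rows, res$net_rows)
    out$nodal_rows <- c(out$nodal_rows, res$nodal_rows)
    out$conn <- c(out$conn, res$conn)
    out$roi_map <- roi_map
    det <- attr(events, "detector")
    if (!is.null(det)) {
      out$rates <- rates_and_iz(det,
                                events$onset_s[events$condition == "IED"])
    }
  }
  if ("hdeeg" %in% modalities) {
    sc <- preprocess(patient$scalp)
    # noise covariance from the control epochs; the mixing sees the same
    # common-average projection as the data
    tf_no <- extract_tf_epochs(sc, events, "no_IED")
    ncov <- noise_covariance(tf_no)
    M_car <- sweep(patient$mixing, 2L, colMeans(patient$mixing))
    inv <- make_inverse_operator(M_car, patient$source_rois, ncov)
    res <- analyze_modality_hd(sc, events, inv, bands, freqs, balance_seed,
                               ied_roi)
    out$tfmaps$hdeeg <- res$tfm
    out$band_rows <- c(out$band_rows, res$band_rows)
    out$net_rows <- c(out$net_rows, res$net_rows)
    out$nodal_rows <- c(out$nodal_rows, res$nodal_rows)
    out$conn <- c(out$conn, res$conn)
  }
  out$band_table <- do.call(rbind, out$band_rows)
  out$net_table <- do.call(rbind, out$net_rows)
  out$nodal_table <- do.call(rbind, out$nodal_rows)
  out$band_rows <- out$net_rows <- out$nodal_rows <- NULL
  out$sampled_rois <- unique(stats::na.omit(patient$channel_map$roi))
  out
}

# hdEEG path: epochs are extracted from the scalp recording and projected
# to region time courses before any measure is computed.
analyze_modality_hd <- function(sc, events, inv, bands, freqs, balance_seed,
                                ied_roi) {
  tf <- balanced_epochs(sc, events, function(cond, nk) {
    extract_tf_epochs(sc, events, cond, nk, balance_seed)
  }, balance_seed)
  tf_roi <- lapply(tf, roi_timecourses, inv = inv)
  tfm <- NULL
  if (ied_roi %in% tf_roi$IED$channel_labels) {
    hip <- lapply(tf_roi, epochs_channel, channel = ied_roi)
    tfm <- c(tf_pair_maps(hip$IED, hip$no_IED, freqs), unit = ied_roi)
  }
  band_rows <- list(); net_rows <- list(); nodal_rows <- list(); conn <- list()
  for (bi in seq_len(nrow(bands))) {
    b <- as.list(bands[bi, ])
    win <- build_window(b, sc$fs)
    eps <- balanced_epochs(sc, events, function(cond, nk) {
      extract_epochs(sc, events, win, cond, nk, balance_seed)
    }, balance_seed)
    eps_roi <- lapply(eps, roi_timecourses, inv = inv)
    for (cond in names(eps_roi)) {
      bm <- band_measures(eps_roi[[cond]], b)
      psd <- bm$psd; itcv <- bm$itc; W <- bm$W
      nm <- network_metrics(W)
      band_rows[[length(band_rows) + 1L]] <- data.frame(
        modality = "hdEEG(ROI)", unit = names(psd), band = b$name,
        condition = cond, power = as.numeric(psd), itc = as.numeric(itcv),
        stringsAsFactors = FALSE)
      nodal_rows[[length(nodal_rows) + 1L]] <- data.frame(
        modality = "hdEEG(ROI)", unit = nm$unit_labels, band = b$name,
        condition = cond, clustering = as.numeric(nm$clustering),
        nodal_efficiency = as.numeric(nm$nodal_efficiency),
        stringsAsFactors = FALSE)
      net_rows[[length(net_rows) + 1L]] <- data.frame(
        modality = "hdEEG(ROI)", band = b$name, condition = cond,
        segregation = nm$mean_clustering, integration = nm$global_efficiency,
        stringsAsFactors = FALSE)
      conn[["hdEEG(ROI)"]][[b$name]][[cond]] <- W
    }
  }
  list(tfm = tfm, band_rows = band_rows, net_rows = net_rows,
       nodal_rows = nodal_rows, conn = conn)
}

pivot_pair <- function(df, value_col) {
  ied <- df[df$condition == "IED", ]
  no <- df[df$condition == "no_IED", ]
  key <- c("patient", "modality", if ("unit" %in% names(df)) "unit", "band")
  m <- merge(ied[, c(key, value_col)], no[, c(key, value_col)],
             by = key, suffixes = c("_IED", "_no_IED"))
  m
}

group_test_units <- function(pair, value_col, q = 0.05) {
  v1 <- paste0(value_col, "_IED"); v2 <- paste0(value_col, "_no_IED")
  keys <- unique(pair[, c("unit", "band")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- pair[pair$unit == keys$unit[i] & pair$band == keys$band[i], ]
    sub <- sub[stats::complete.cases(sub[, c(v1, v2)]), ]
    if (nrow(sub) < 5L) return(NULL)
    wt <- tryCatch(wilcoxon_one_sided(sub[[v1]], sub[[v2]]),
                   error = function(e) NULL)
    if (is.null(wt)) return(NULL)
    data.frame(unit = keys$unit[i], band = keys$band[i],
               n = nrow(sub), median_diff = wt$median_diff, p = wt$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(NULL)
  adj <- fdr_bh(tab$p, q)
  tab$p_adj <- adj$p_adj
  tab$significant <- adj$significant
  tab
}

#' Run the full pipeline on a synthetic (or supplied) cohort
#'
#' Generates (or consumes) a cohort, analyzes every patient, and runs the
#' group statistics: cluster-based sign-flip permutation tests on the
#' hippocampal ERSP/ITC maps (cluster-forming p 0.0005 / cluster p 0.001
#' for ERSP; 0.05 / 0.05 for ITC), and one-sided Wilcoxon signed-rank
#' tests with BH-FDR for band, region and whole-network measures. Region
#' tests are restricted to regions sampled in at least `min_patients`
#' patients.
#'
#' @param cfg A [synth_config()], or a list of patients from
#'   [synth_cohort()] / your own loader.
#' @param modalities Subset of `c("ieeg", "hdeeg")`.
#' @param q FDR level.
#' @param min_patients Region sampling gate (default 5).
#' @param alphas Cluster-test levels, a list with `ersp_form`,
#'   `ersp_cluster`, `itc_form`, `itc_cluster`.
#' @param balance_seed Seed for the equal-count epoch subsampling.
#' @param cluster_kinds Which hippocampal map contrasts get a cluster test
#'   (subset of `c("ersp", "itc")`).
#' @return Object of class `iednet_results`: per-patient tables stacked in
#'   `band_table` / `nodal_table` / `net_table`, group-test tables
#'   (`roi_tests`, `network_tests`), cluster tests (`cluster_tests`),
#'   rate tables, the sampling gate, and a machine-readable `log`.
#' @export
run_pipeline <- function(cfg, modalities = c("ieeg", "hdeeg"), q = 0.05,
                         min_patients = 5L,
                         alphas = list(ersp_form = 5e-4, ersp_cluster = 1e-3,
                                       itc_form = 0.05, itc_cluster = 0.05),
                         balance_seed = 1L,
                         cluster_kinds = c("ersp", "itc")) {
  cohort <- if (inherits(cfg, "synth_config")) {
    synth_cohort(cfg, include_scalp = "hdeeg" %in% modalities)
  } else cfg
  pats <- lapply(cohort, analyze_patient, modalities = modalities,
                 balance_seed = balance_seed)
  n <- length(pats)
  stack <- function(field) {
    do.call(rbind, lapply(pats, function(p) {
      if (is.null(p[[field]])) return(NULL)
      cbind(patient = p$patient_index, p[[field]])
    }))
  }
  band_table <- stack("band_table")
  nodal_table <- stack("nodal_table")
  net_table <- stack("net_table")

  sampled <- table(unlist(lapply(pats, `[[`, "sampled_rois")))
  gate_units <- names(sampled)[sampled >= min_patients]

  roi_tests <- list()
  for (mod in unique(band_table$modality)) {
    for (measure in c("power", "itc", "clustering", "nodal_efficiency")) {
      src <- if (measure %in% c("power", "itc")) band_table else nodal_table
      sub <- src[src$modality == mod, ]
      if (mod %in% c("iEEG(ROI)", "hdEEG(ROI)") && length(gate_units)) {
        sub <- sub[sub$unit %in% gate_units, ]
      }
      if (nrow(sub) == 0L) next
      pair <- pivot_pair(sub, measure)
      tab <- group_test_units(pair, measure, q)
      if (!is.null(tab)) {
        roi_tests[[length(roi_tests) + 1L]] <-
          cbind(modality = mod, measure = measure, tab)
      }
    }
  }
  roi_tests <- do.call(rbind, roi_tests)

  network_tests <- list()
  for (mod in unique(net_table$modality)) {
    for (measure in c("integration", "segregation")) {
      sub <- net_table[net_table$modality == mod, ]
      pair <- pivot_pair(cbind(sub, unit = "network"), measure)
      tab <- group_test_units(pair, measure, q)
      if (is.null(tab)) next
      v1 <- paste0(measure, "_IED"); v2 <- paste0(measure, "_no_IED")
      tab$n_increase <- vapply(tab$band, function(b) {
        s <- pair[pair$band == b, ]
        sum(s[[v1]] > s[[v2]])
      }, numeric(1))
      network_tests[[length(network_tests) + 1L]] <-
        cbind(modality = mod, measure = measure, tab[, names(tab) != "unit"])
    }
  }
  network_tests <- do.call(rbind, network_tests)

  cluster_tests <- list()
  for (mod in names(pats[[1]]$tfmaps)) {
    maps <- lapply(pats, function(p) p$tfmaps[[mod]])
    if (any(vapply(maps, is.null, logical(1)))) next
    cm <- coi_mask(maps[[1]]$ersp_IED)
    ct <- list()
    if ("ersp" %in% cluster_kinds) {
      ct$ersp <- cluster_permutation(lapply(maps, `[[`, "ersp_IED"),
                                     lapply(maps, `[[`, "ersp_no_IED"),
                                     alpha_form = alphas$ersp_form,
                                     alpha_cluster = alphas$ersp_cluster,
                                     coi = cm)
    }
    if ("itc" %in% cluster_kinds) {
      ct$itc <- cluster_permutation(lapply(maps, `[[`, "itc_IED"),
                                    lapply(maps, `[[`, "itc_no_IED"),
                                    alpha_form = alphas$itc_form,
                                    alpha_cluster = alphas$itc_cluster,
                                    coi = cm)
    }
    cluster_tests[[mod]] <- ct
  }

  rates <- do.call(rbind, lapply(pats, function(p) {
    if (is.null(p$rates)) NULL else cbind(patient = p$patient_index, p$rates)
  }))

  structure(list(
    band_table = band_table, nodal_table = nodal_table,
    net_table = net_table, roi_tests = roi_tests,
    network_tests = network_tests, cluster_tests = cluster_tests,
    rates = rates, gate_units = gate_units,
    sampled_counts = as.data.frame(sampled, stringsAsFactors = FALSE),
    patients = pats,
    log = list(n_patients = n, modalities = modalities, q = q,
               min_patients = min_patients, alphas = alphas,
               balance_seed = balance_seed,
               wpli_estimator = "wPLI (non-debiased, across trials)",
               clustering_variant = "Onnela weighted clustering",
               roi_svd = "per-epoch first singular vector, sign to ROI mean",
               package_version = as.character(utils::packageVersion("iednet")))),
    class = "iednet_results")
}

#' @export
print.iednet_results <- function(x, ...) {
  cat(sprintf("<iednet_results> %d patient(s); %d region test(s) (%d significant); %d network test(s) (%d significant)\n",
              x$log$n_patients,
              if (is.null(x$roi_tests)) 0L else nrow(x$roi_tests),
              if (is.null(x$roi_tests)) 0L else sum(x$roi_tests$significant),
              if (is.null(x$network_tests)) 0L else nrow(x$network_tests),
              if (is.null(x$network_tests)) 0L else sum(x$network_tests$significant)))
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Tabular outputs as TSV, cluster reports and the run log as JSON.
#'
#' @param results An `iednet_results`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) utils::write.table(df, file.path(dir, name),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
  }
  wt(results$band_table, "band_table.tsv")
  wt(results$nodal_table, "nodal_table.tsv")
  wt(results$net_table, "network_table.tsv")
  wt(results$roi_tests, "roi_tests.tsv")
  wt(results$network_tests, "network_tests.tsv")
  wt(results$rates, "rates.tsv")
  cl <- lapply(results$cluster_tests, function(m) {
    lapply(m, function(ct) ct$clusters)
  })
  jsonlite::write_json(cl, file.path(dir, "cluster_tests.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(results$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
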