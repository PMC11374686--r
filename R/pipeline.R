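# End-to-end orchestration and summary fractions.

#' Run the full analysis pipeline on a session
#'
#' Executes segmentation, trajectory clustering, rate maps, spatial
#' information across reference frames, identity/presence permutation tests
#' (including the conspecific-excluded control), the conjunctive-coding
#' linear model, and 1D remapping metrics, for every unit in the session.
#'
#' @param sess a [Session-class] (e.g. from [loadSession()] or
#'   [simulateSession()]).
#' @param outDir optional directory: results are written as TSV tables plus
#'   a JSON run manifest (config + seed).
#' @param seed global seed (defaults to the session config's seed);
#'   per-test substreams are derived from it.
#' @param frames which SI reference frames to run (default all available).
#' @return named list of data.frames: si, identity, conjunctive, remap,
#'   plus the precomputed behavioral `frames`.
#' @export
runAll <- function(sess, outDir = NULL, seed = NULL,
                   frames = c("self_2d", "self_1d", "conspecific_1d",
                              "human_2d_pooled", "human_2d_identity")) {
  cfg <- sess@config
  p <- cfg@params
  seed <- seed %||% p$seed
  fr <- sessionFrames(sess)

  siRows <- list(); idRows <- list(); cjRows <- list(); rmRows <- list()
  for (ui in seq_along(sess@units)) {
    u <- sess@units[[ui]]
    spikes <- u@spikes@times
    for (f in frames) {
      r <- tryCatch(siByFrame(sess, u, f, fr, deriveSeed(seed, ui)),
                    error = function(e) NULL)
      if (!is.null(r)) siRows[[length(siRows) + 1]] <- r
    }
    idRows[[length(idRows) + 1]] <-
      identityModulation(spikes, fr$flights, c("landing", "takeoff"),
                         FALSE, cfg, deriveSeed(seed, ui, 1L), u@unitId)
    idRows[[length(idRows) + 1]] <-
      identityModulation(spikes, fr$flights, "landing", TRUE, cfg,
                         deriveSeed(seed, ui, 2L), u@unitId)
    if (!is.null(fr$other))
      idRows[[length(idRows) + 1]] <-
        presenceModulation(spikes, fr$flights, cfg,
                           deriveSeed(seed, ui, 3L), u@unitId)

    tr <- eventTrials(spikes, fr$flights, "landing", cfg)
    tr <- tr[!is.na(tr$location) & !is.na(tr$human), , drop = FALSE]
    cj <- data.frame(unit = u@unitId, p_human = NA_real_,
                     p_location = NA_real_, p_interaction = NA_real_,
                     coding_class = NA_character_)
    if (nrow(tr) >= 8 && length(unique(tr$human)) >= 2 &&
        length(unique(tr$location)) >= 2 && sd(tr$rate) > 0) {
      fit <- tryCatch(fitLandingModel(tr$rate, tr$human, tr$location),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        cj$p_human <- fit$p_human
        cj$p_location <- fit$p_location
        cj$p_interaction <- fit$p_interaction
        cj$coding_class <- classifyCoding(fit$p_human, fit$p_location,
                                          fit$p_interaction, p$alpha)
      }
    }
    cjRows[[length(cjRows) + 1]] <- cj

    # 1D remapping per trajectory with both-human inclusion
    if (!is.null(fr$clusters)) {
      fl <- fr$flights
      for (k in sort(unique(fr$clusters))) {
        sub <- fl[fr$clusters == k & !is.na(fl$human_at_landing), ,
                  drop = FALSE]
        hs <- unique(sub$human_at_landing)
        if (length(hs) != 2) next
        okBoth <- all(vapply(hs, function(h)
          analyzable1D(sub[sub$human_at_landing == h, ], spikes,
                       p$minFlights1D, p$minFlightsWithSpikes1D,
                       p$minSpikes1D), logical(1)))
        if (!okBoth) next
        m1 <- rateMap1D(fr$bat, sub[sub$human_at_landing == hs[1], ],
                        spikes, cfg, checkInclusion = FALSE)
        m2 <- rateMap1D(fr$bat, sub[sub$human_at_landing == hs[2], ],
                        spikes, cfg, checkInclusion = FALSE)
        mm <- mapMetrics1D(m1, m2)
        ns <- nullTrialShuffle(
          data.frame(start_s = sub$start_s, end_s = sub$end_s,
                     human = sub$human_at_landing),
          spikes, p$nShuffles, deriveSeed(seed, ui, 10L + k))
        rmRows[[length(rmRows) + 1]] <- data.frame(
          unit = u@unitId, trajectory = paste0("traj", k),
          pearson_r = mm$pearson_r, peak_distance_m = mm$peak_distance_m,
          score = ns$empirical,
          score_null_p95 = as.numeric(quantile(ns$null, 0.95, na.rm = TRUE)),
          rate_h1 = ns$rates[1], rate_h2 = ns$rates[2])
      }
    }
  }

  res <- list(
    si = if (length(siRows)) do.call(rbind, siRows) else NULL,
    identity = if (length(idRows)) do.call(rbind, idRows) else NULL,
    conjunctive = if (length(cjRows)) do.call(rbind, cjRows) else NULL,
    remap = if (length(rmRows)) do.call(rbind, rmRows) else NULL,
    frames = fr)

  if (!is.null(outDir)) {
    tabs <- res[!vapply(res, is.null, logical(1))]
    tabs$frames <- NULL
    writeReportTables(tabs, outDir)
    manifest <- list(seed = seed, config = cfg@params,
                     n_units = length(sess@units),
                     r_version = as.character(getRversion()))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Population summary fractions from pipeline results
#'
#' Fractions are reported over analyzable units only (rows with
#' non-missing significance), matching the "analyzable units" convention:
#' every unit is either significant, not significant, or not analyzable per
#' test family.
#'
#' @param results from [runAll()].
#' @return data.frame(measure, n_significant, n_analyzable, fraction,
#'   formatted) with one row per test family.
#' @export
summarizeResults <- function(results) {
  rows <- list()
  addRow <- function(measure, sig) {
    sig <- sig[!is.na(sig)]
    n <- length(sig); k <- sum(sig)
    rows[[length(rows) + 1]] <<- data.frame(
      measure = measure, n_significant = k, n_analyzable = n,
      fraction = if (n > 0) k / n else NA_real_,
      formatted = formatFraction(k, n))
  }
  si <- results$si
  if (!is.null(si)) {
    perUnit <- function(frame) {
      sub <- si[si$frame == frame, , drop = FALSE]
      if (!nrow(sub)) return(logical(0))
      vapply(unique(sub$unit), function(u) {
        s <- sub$significant[sub$unit == u]
        if (all(is.na(s))) NA else any(s, na.rm = TRUE)
      }, logical(1))
    }
    addRow("si_2d_self", perUnit("self_2d"))
    addRow("si_1d_self", perUnit("self_1d"))
    addRow("si_conspecific", perUnit("conspecific_1d"))
    addRow("si_human_pooled", perUnit("human_2d_pooled"))
    addRow("si_human_identity", perUnit("human_2d_identity"))
    # among identity-frame-significant units: one human vs both
    sub <- si[si$frame == "human_2d_identity", , drop = FALSE]
    if (nrow(sub)) {
      nSig <- vapply(unique(sub$unit), function(u)
        sum(sub$significant[sub$unit == u], na.rm = TRUE), numeric(1))
      addRow("human_identity_one_human", nSig[nSig > 0] == 1)
    }
  }
  idt <- results$identity
  if (!is.null(idt)) {
    perVariant <- function(variant) {
      sub <- idt[idt$variant == variant, , drop = FALSE]
      if (!nrow(sub)) return(logical(0))
      vapply(unique(sub$unit), function(u) {
        s <- sub$significant[sub$unit == u]
        if (all(is.na(s))) NA else any(s, na.rm = TRUE)
      }, logical(1))
    }
    addRow("identity_modulated", perVariant("full"))
    addRow("identity_modulated_no_conspecific",
           perVariant("conspecific_excluded"))
    addRow("conspecific_presence_modulated", perVariant("presence"))
  }
  cj <- results$conjunctive
  if (!is.null(cj)) {
    known <- cj$coding_class[!is.na(cj$coding_class)]
    addRow("coding_class_assigned", known != "none")
  }
  do.call(rbind, rows)
}
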