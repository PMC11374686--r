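# Session directory layout:
#   tracking.csv          time_s,subject,tag,x_m,y_m,z_m (one row per sample)
#   spikes/<unit_id>.txt  one spike timestamp (s) per line
#   config.yaml           geometry, subject roles, block schedule, events,
#                         reward volumes, analysis parameters

#' Load a session from its on-disk representation
#'
#' Reads a headered tracking CSV, per-unit spike-time files and a YAML config
#' into a validated [Session-class]. Rows are re-sorted by time per
#' subject/tag (with a warning if any were out of order); duplicate
#' timestamps are dropped; gaps are linearly interpolated onto the nominal
#' 100 Hz grid, and gaps longer than 0.5 s are flagged in the QC log
#' (retrievable with [qcLog()]).
#'
#' @param tracking path to tracking.csv, or a session directory containing
#'   `tracking.csv`, `spikes/` and `config.yaml`.
#' @param spikes path to the spikes directory (one `.txt` per unit).
#' @param config path to config.yaml.
#' @return a [Session-class] with a QC log attached.
#' @export
loadSession <- function(tracking, spikes = NULL, config = NULL) {
  if (dir.exists(tracking)) {
    dir <- tracking
    tracking <- file.path(dir, "tracking.csv")
    spikes <- spikes %||% file.path(dir, "spikes")
    config <- config %||% file.path(dir, "config.yaml")
  }
  for (f in c(tracking, config)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  cfg <- yaml::yaml.load_file(config)
  geom <- geometryFromList(cfg$geometry)
  acfg <- do.call(analysisConfig, cfg$analysis %||% list())

  trk <- tryCatch(read.csv(tracking, stringsAsFactors = FALSE),
                  error = function(e) stop("parse error in ", tracking, ": ",
                                           conditionMessage(e)))
  need <- c("time_s", "subject", "tag", "x_m", "y_m", "z_m")
  if (!all(need %in% names(trk)))
    stop("tracking file must have columns ", paste(need, collapse = ","))
  for (col in c("time_s", "x_m", "y_m", "z_m"))
    trk[[col]] <- suppressWarnings(as.numeric(trk[[col]]))
  bad <- which(!complete.cases(trk[need]))
  if (length(bad))
    stop(sprintf("malformed tracking row(s) at line(s) %s",
                 paste(head(bad + 1, 5), collapse = ", ")))

  known <- c(cfg$subjects$bats, cfg$subjects$humans)
  unknown <- setdiff(unique(trk$subject), known)
  if (length(unknown))
    stop("unknown subject id(s) in tracking: ", paste(unknown, collapse = ", "))

  qc <- data.frame(subject = character(0), tag = character(0),
                   issue = character(0), detail = character(0))
  makeSeries <- function(sub, tag) {
    d <- trk[trk$subject == sub & trk$tag == tag, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    if (is.unsorted(d$time_s)) {
      warning(sprintf("re-sorted out-of-order samples for %s/%s", sub, tag))
      d <- d[order(d$time_s), , drop = FALSE]
    }
    d <- d[!duplicated(d$time_s), , drop = FALSE]
    ts <- d$time_s
    xyz <- cbind(d$x_m, d$y_m, d$z_m)
    dtg <- diff(ts)
    dt <- median(dtg)
    gaps <- which(dtg > 0.5)
    for (g in gaps) {
      qc <<- rbind(qc, data.frame(
        subject = sub, tag = tag, issue = "tracking_gap",
        detail = sprintf("%.2f s gap at t=%.2f", dtg[g], ts[g])))
    }
    if (any(dtg > 1.5 * dt)) { # resample onto the regular grid
      grid <- seq(ts[1], ts[length(ts)], by = dt)
      xyz <- cbind(approx(ts, xyz[, 1], grid)$y,
                   approx(ts, xyz[, 2], grid)$y,
                   approx(ts, xyz[, 3], grid)$y)
      ts <- grid
    }
    trackedSeries(sub, tag, ts, xyz)
  }

  bats <- list()
  recorded <- cfg$subjects$recorded %||% cfg$subjects$bats[[1]]
  for (b in c(recorded, setdiff(unlist(cfg$subjects$bats), recorded))) {
    s <- makeSeries(b, "body")
    if (!is.null(s)) bats[[length(bats) + 1]] <- s
  }
  humans <- list()
  for (h in unlist(cfg$subjects$humans)) {
    tags <- list()
    for (tg in c("coat", "left_hand", "right_hand")) {
      s <- makeSeries(h, tg)
      if (!is.null(s)) tags[[tg]] <- s
    }
    humans[[h]] <- tags
  }

  span <- range(unlist(lapply(bats, function(s) range(s@timestamps))))
  units <- list()
  if (!is.null(spikes) && dir.exists(spikes)) {
    for (f in sort(list.files(spikes, pattern = "\\.txt$", full.names = TRUE))) {
      uid <- sub("\\.txt$", "", basename(f))
      raw <- readLines(f)
      raw <- raw[nzchar(trimws(raw))]
      tms <- suppressWarnings(as.numeric(raw))
      if (anyNA(tms)) {
        bad <- which(is.na(tms))[1]
        stop(sprintf("parse error in %s at line %d", f, bad))
      }
      tms <- tms[tms >= span[1] & tms <= span[2]]
      units[[length(units) + 1]] <- unitRecord(spikeTrain(uid, tms, span))
    }
  }

  sched <- scheduleFromList(cfg$schedule)
  ev <- eventsFromList(cfg$events)
  rw <- unlist(cfg$reward_volumes %||% list())
  rw <- if (is.null(rw)) numeric(0) else rw
  out <- session(geom, bats, humans, units, sched, ev, rw, acfg)
  attr(out, "qc") <- qc
  out
}

#' QC log attached to a loaded session
#' @param session a [Session-class] returned by [loadSession()].
#' @return data.frame(subject, tag, issue, detail).
#' @export
qcLog <- function(session) {
  attr(session, "qc") %||%
    data.frame(subject = character(0), tag = character(0),
               issue = character(0), detail = character(0))
}

#' Write a session to a directory in the package's plain-text formats
#'
#' Inverse of [loadSession()]: round trips are exact to 1e-6 s.
#'
#' @param session a [Session-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  addSeries <- function(s) {
    rows[[length(rows) + 1]] <<- data.frame(
      time_s = round(s@timestamps, 6), subject = s@subjectId, tagn = s@tagId,
      x_m = round(s@xyz[, 1], 6), y_m = round(s@xyz[, 2], 6),
      z_m = round(s@xyz[, 3], 6))
  }
  for (b in session@bats) addSeries(b)
  for (h in session@humans) for (s in h) addSeries(s)
  trk <- do.call(rbind, rows)
  names(trk)[3] <- "tag"
  trk <- trk[order(trk$time_s, trk$subject, trk$tag), ]
  write.csv(trk, file.path(dir, "tracking.csv"), row.names = FALSE,
            quote = FALSE)

  spkdir <- file.path(dir, "spikes")
  dir.create(spkdir, showWarnings = FALSE)
  for (u in session@units) {
    writeLines(sprintf("%.6f", u@spikes@times),
               file.path(spkdir, paste0(u@unitId, ".txt")))
  }

  cfg <- list(
    geometry = geometryToList(session@geometry),
    subjects = list(
      bats = lapply(session@bats, function(b) b@subjectId),
      recorded = session@bats[[1]]@subjectId,
      humans = as.list(names(session@humans))
    ),
    schedule = lapply(seq_len(nrow(session@schedule)), function(i)
      as.list(session@schedule[i, ])),
    events = lapply(seq_len(nrow(session@events)), function(i)
      as.list(session@events[i, ])),
    reward_volumes = as.list(session@rewardVolumes),
    analysis = session@config@params
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

geometryToList <- function(g) {
  list(extent = as.numeric(g@extent),
       tripods = setNames(lapply(seq_len(nrow(g@tripods)),
                                 function(i) as.numeric(g@tripods[i, ])),
                          rownames(g@tripods)),
       traverse_start = as.numeric(g@traverseStart),
       rest_centroids = lapply(seq_len(nrow(g@restCentroids)),
                               function(i) as.numeric(g@restCentroids[i, ])))
}

geometryFromList <- function(l) {
  tp <- do.call(rbind, l$tripods)
  rownames(tp) <- names(l$tripods)
  rc <- if (length(l$rest_centroids)) do.call(rbind, l$rest_centroids)
        else matrix(numeric(0), 0, 3)
  roomGeometry(extent = unlist(l$extent), tripods = tp,
               traverseStart = unlist(l$traverse_start), restCentroids = rc)
}

scheduleFromList <- function(l) {
  if (is.null(l) || !length(l))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      human = character(0), tripod = character(0)))
  do.call(rbind, lapply(l, function(r)
    data.frame(start_s = as.numeric(r$start_s), end_s = as.numeric(r$end_s),
               human = r$human, tripod = r$tripod)))
}

eventsFromList <- function(l) {
  if (is.null(l) || !length(l)) return(emptyEvents())
  do.call(rbind, lapply(l, function(r)
    data.frame(start_s = as.numeric(r$start_s), end_s = as.numeric(r$end_s),
               human = r$human, kind = r$kind)))
}

#' Format a count pair as "X% (n out of m)"
#'
#' @param n numerator count.
#' @param m denominator count.
#' @param digits decimal places for the percentage (default 1).
#' @return character; "n/a" when m is 0.
#' @export
formatFraction <- function(n, m, digits = 1) {
  if (m == 0) return("n/a")
  sprintf("%s (%d out of %d)", formatPercent(n, m, digits), n, m)
}

#' @rdname formatFraction
#' @export
formatPercent <- function(n, m, digits = 1) {
  if (m == 0) return("n/a")
  sprintf(paste0("%.", digits, "f%%"), 100 * n / m)
}

#' Write per-unit test-result tables as TSV with a fraction footer
#'
#' Each element of `results` is a data.frame with one row per unit x test
#' (empirical statistic, null summary, p, Bonferroni-corrected significance
#' in a logical `significant` column) written as `<name>.tsv`. A commented
#' footer line reports the significant fraction as "X% (n out of m)" over
#' rows where `significant` is not NA (not-analyzable rows are excluded from
#' the denominator).
#'
#' @param results named list of data.frames.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
writeReportTables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    path <- file.path(dir, paste0(nm, ".tsv"))
    ok <- tryCatch({
      write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) stop("failed to write ", path, ": ",
                                conditionMessage(e)))
    if (ok && "significant" %in% names(df)) {
      sig <- df$significant[!is.na(df$significant)]
      cat(sprintf("# significant: %s\n",
                  formatFraction(sum(sig), length(sig))),
          file = path, append = TRUE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
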