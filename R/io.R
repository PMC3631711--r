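# On-disk formats: per-trial CSV with '#' key=value header lines, and a JSON
# session manifest. Float columns use fixed "%.9f" formatting so writing the
# same trial twice is byte-identical and read(write(x)) round-trips to 1e-9.

TRIAL_COLUMNS <- c("i", "hx", "hy", "hz", "px", "py", "pz",
                   "qw", "qx", "qy", "qz")

fmt_num <- function(x) {
  out <- sprintf("%.9f", x)
  sub("^-(0\\.0{9})$", "\\1", out)  # avoid "-0.000000000"
}

#' Write one trial to a CSV file
#'
#' The file starts with `#`-prefixed `key=value` metadata lines (subject,
#' condition, target azimuth, stimulus duration, sampling rate, avatar
#' shift, start marker), followed by a header row and the sample table with
#' columns `i, hx, hy, hz, px, py, pz, qw, qx, qy, qz` (h = hand position,
#' p/q = head position/orientation quaternion, scalar first).
#'
#' @param trial A [trial_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  m <- trial$meta
  hand <- trial$hand; head <- trial$head
  if (length(hand) != length(head) || hand$i0 != head$i0) {
    stop("write_trial: hand and head must share one sample grid")
  }
  hdr <- c(
    sprintf("# subject=%s", m$subject_id),
    sprintf("# condition=%s", m$condition),
    sprintf("# target_azimuth_deg=%s", fmt_num(m$target_azimuth_deg)),
    sprintf("# stimulus_duration_ms=%s", fmt_num(m$stimulus_duration_ms)),
    sprintf("# trial_index=%d", m$trial_index),
    sprintf("# fs=%s", fmt_num(hand$fs)),
    sprintf("# i0=%d", hand$i0),
    sprintf("# avatar_shift_deg=%s", fmt_num(m$avatar_shift_deg)),
    sprintf("# start_marker=%s,%s,%s",
            fmt_num(trial$start_marker[1]), fmt_num(trial$start_marker[2]),
            fmt_num(trial$start_marker[3])),
    "# quaternion=scalar-first,world-from-body",
    "# frame=x-right,y-forward,z-up"
  )
  idx <- hand$i0 + seq_len(length(hand)) - 1L
  num <- cbind(hand$p, head$p, head$q)
  body <- paste(idx, apply(num, 1, function(r)
    paste(fmt_num(r), collapse = ",")), sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(TRIAL_COLUMNS, collapse = ","), body), con,
             sep = "\n")
  invisible(path)
}

parse_trial_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Read one trial from a CSV file written by [write_trial()]
#'
#' @param path Path to a trial CSV file.
#' @return A [trial_record()]; sample count, metadata and all coordinates
#'   are restored to within 1e-9 of the written values.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("read_trial: no such file: ", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  meta <- parse_trial_header(lines[is_hdr])
  needed <- c("subject", "condition", "target_azimuth_deg",
              "stimulus_duration_ms", "fs", "avatar_shift_deg",
              "start_marker")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    stop("read_trial: malformed header, missing: ",
         paste(missing, collapse = ", "))
  }
  tab_lines <- lines[!is_hdr]
  if (length(tab_lines) < 2 ||
      !identical(tab_lines[1], paste(TRIAL_COLUMNS, collapse = ","))) {
    stop("read_trial: malformed column header in ", path)
  }
  dat <- utils::read.csv(text = tab_lines, header = TRUE)
  bad <- which(!stats::complete.cases(dat) |
                 !apply(as.matrix(dat), 1, function(r) all(is.finite(r))))
  if (length(bad) > 0) {
    stop(sprintf("read_trial: non-finite value at data row %d of %s",
                 bad[1], path))
  }
  i0 <- as.integer(if (!is.null(meta$i0)) meta$i0 else dat$i[1])
  if (any(diff(dat$i) != 1)) {
    stop(sprintf("read_trial: non-uniform sample index at data row %d",
                 which(diff(dat$i) != 1)[1] + 1))
  }
  fs <- as.numeric(meta$fs)
  tm <- trial_meta(
    subject_id = meta$subject,
    condition = meta$condition,
    target_azimuth_deg = as.numeric(meta$target_azimuth_deg),
    trial_index = as.integer(if (!is.null(meta$trial_index)) meta$trial_index else 0L),
    stimulus_duration_ms = as.numeric(meta$stimulus_duration_ms),
    avatar_shift_deg = as.numeric(meta$avatar_shift_deg)
  )
  hand <- trajectory_series(as.matrix(dat[, c("hx", "hy", "hz")]), fs, i0)
  q <- as.matrix(dat[, c("qw", "qx", "qy", "qz")])
  nrm <- sqrt(rowSums(q^2))
  off <- which(abs(nrm - 1) > 1e-6)
  if (length(off) > 0) {
    stop(sprintf("read_trial: non-unit quaternion at data row %d of %s",
                 off[1], path))
  }
  head <- head_pose_series(as.matrix(dat[, c("px", "py", "pz")]), q, fs, i0)
  sm <- as.numeric(strsplit(meta$start_marker, ",", fixed = TRUE)[[1]])
  trial_record(tm, hand, head, sm)
}

#' Write a session (trials + manifest) to a directory
#'
#' @param trials List of [trial_record()] objects, in presentation order.
#' @param config A [session_config()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(trials, config, dir) {
  stopifnot(inherits(config, "session_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(trials))
  for (k in seq_along(trials)) {
    files[k] <- sprintf("trial_%03d_%s_%+03d.csv", k - 1L,
                        trials[[k]]$meta$condition,
                        as.integer(trials[[k]]$meta$target_azimuth_deg))
    write_trial(trials[[k]], file.path(dir, files[k]))
  }
  manifest <- list(
    subject_id = config$subject_id,
    condition_order = config$condition_order,
    trials_per_session = config$trials_per_session,
    seed = config$seed,
    hrtf_individual = config$hrtf_individual,
    trial_files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' Load a session directory written by [write_session()]
#'
#' Trials are returned exactly in manifest order; the loader never reorders.
#'
#' @param dir Session directory containing `manifest.json` and trial files.
#' @return A list with `trials` (list of [trial_record()]) and `config`
#'   (a [session_config()]).
#' @export
load_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("load_session: no manifest.json in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- man$trial_files
  if (is.null(files)) files <- character(0)
  trials <- vector("list", length(files))
  for (k in seq_along(files)) {
    fp <- file.path(dir, files[k])
    if (!file.exists(fp)) {
      stop("load_session: manifest lists missing trial file: ", files[k])
    }
    trials[[k]] <- read_trial(fp)
  }
  cfg <- session_config(
    subject_id = man$subject_id,
    condition_order = man$condition_order,
    trials_per_session = man$trials_per_session,
    seed = man$seed,
    hrtf_individual = isTRUE(man$hrtf_individual)
  )
  list(trials = trials, config = cfg)
}
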