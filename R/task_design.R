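#' Generate a passive auditory oddball task schedule
#'
#' Builds the trial list for one subject: 4 blocks of 103 trials each. Every
#' block starts with 3 standard tones that establish the standard, followed by
#' 100 pseudorandom tones of which 20 (20%) are oddballs. Tones last 100 ms and
#' are separated by an interstimulus interval jittered uniformly between 1800
#' and 2000 ms. Oddball and standard pitch (500 vs 750 Hz) are assigned
#' pseudo-randomly per subject for the first block and swapped between the two
#' blocks of each manipulation phase, so that within each phase both pitches
#' serve as the oddball once. The arousal manipulation (handgrip exercise)
#' separates blocks 2 and 3: blocks 1-2 are labelled `before`, blocks 3-4
#' `after`.
#'
#' @param subject_id Identifier stored with the schedule.
#' @param seed Non-negative integer seed; schedules are reproducible per seed.
#' @param forbid_consecutive_oddballs If `TRUE` (default) the pseudorandom
#'   portion never contains two adjacent oddballs, so every oddball is preceded
#'   by at least one standard.
#' @param n_blocks Number of blocks (default 4; smaller values are only useful
#'   for reduced smoke-test designs).
#' @param blocks Block indices to retain (default all). A reduced design such
#'   as `blocks = c(1, 3)` keeps one block per manipulation phase; the full
#'   4-block schedule is generated first, so retained blocks are identical to
#'   their counterparts in the complete design.
#' @return An object of class `task_schedule`: a list with `subject_id`,
#'   `manipulation_after_block` and `trials`, a `data.frame` with one row per
#'   trial (`block`, `index_in_block`, `stimulus`, `pitch_hz`, `tone_duration_ms`,
#'   `isi_ms`, `onset_ms`, `manipulation_phase`, `block_direction`).
#' @examples
#' sched <- build_schedule("s01", seed = 1)
#' table(sched$trials$block, sched$trials$stimulus)
#' @export
build_schedule <- function(subject_id, seed,
                           forbid_consecutive_oddballs = TRUE,
                           n_blocks = 4L, blocks = seq_len(n_blocks)) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1L, n_blocks <= 4L, all(blocks %in% seq_len(n_blocks)))
  trials <- with_seed(seed, {
    pitches <- c(500, 750)
    first_oddball <- sample(pitches, 1L) # pseudo-random between subjects
    other <- setdiff(pitches, first_oddball)
    block_list <- lapply(seq_len(n_blocks), function(b) {
      direction <- if (b %% 2L == 1L) "forward" else "reverse"
      oddball_pitch <- if (direction == "forward") first_oddball else other
      standard_pitch <- setdiff(pitches, oddball_pitch)
      stim <- c(rep("standard", 3L),
                pseudorandom_stimuli(100L, 20L, forbid_consecutive_oddballs))
      isi <- sample_isi(length(stim))
      onset <- cumsum(c(0, head(100 + isi, -1L)))
      data.frame(
        block = b,
        index_in_block = seq_along(stim),
        stimulus = stim,
        pitch_hz = ifelse(stim == "oddball", oddball_pitch, standard_pitch),
        tone_duration_ms = 100,
        isi_ms = isi,
        onset_ms = onset,
        manipulation_phase = if (b <= 2L) "before" else "after",
        block_direction = direction,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, block_list)
  })
  trials <- trials[trials$block %in% blocks, , drop = FALSE]
  rownames(trials) <- NULL
  structure(
    list(subject_id = subject_id, manipulation_after_block = 2L,
         trials = trials, seed = seed),
    class = "task_schedule"
  )
}

# 80/20 pseudorandom stimulus order. With the adjacency constraint the oddball
# positions are drawn uniformly from all placements of `n_odd` non-adjacent
# slots among `n` (stars-and-bars construction).
pseudorandom_stimuli <- function(n, n_odd, forbid_consecutive = TRUE) {
  if (forbid_consecutive) {
    stopifnot(n - n_odd + 1L >= n_odd)
    pos <- sort(sample.int(n - n_odd + 1L, n_odd)) + seq_len(n_odd) - 1L
  } else {
    pos <- sort(sample.int(n, n_odd))
  }
  stim <- rep("standard", n)
  stim[pos] <- "oddball"
  stim
}

#' Draw jittered interstimulus intervals
#'
#' Uniform draws on the closed interval 1800 to 2000 ms, using the current RNG
#' state.
#'
#' @param n Number of draws.
#' @param min_ms,max_ms Jitter bounds in ms.
#' @return Numeric vector of ISIs in ms.
#' @export
sample_isi <- function(n = 1L, min_ms = 1800, max_ms = 2000) {
  runif(n, min_ms, max_ms)
}

#' Per-block pitch assignment of a schedule
#'
#' @param schedule A `task_schedule`.
#' @return A `data.frame` with one row per block: `block`, `oddball_pitch_hz`,
#'   `standard_pitch_hz`, `manipulation_phase`, `block_direction`.
#' @export
pitch_assignment <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  tr <- schedule$trials
  out <- lapply(split(tr, tr$block), function(b) {
    data.frame(
      block = b$block[1L],
      oddball_pitch_hz = unique(b$pitch_hz[b$stimulus == "oddball"]),
      standard_pitch_hz = unique(b$pitch_hz[b$stimulus == "standard"]),
      manipulation_phase = b$manipulation_phase[1L],
      block_direction = b$block_direction[1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.task_schedule <- function(x, ...) {
  tr <- x$trials
  cat("<task_schedule> subject", x$subject_id,
      "-", length(unique(tr$block)), "blocks,", nrow(tr), "trials\n")
  print(table(block = tr$block, stimulus = tr$stimulus))
  invisible(x)
}

#' Write / read a schedule as TSV
#'
#' The on-disk layout has one row per trial with a leading `subject_id`
#' column, matching the CLI contract.
#'
#' @param schedule A `task_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   a `task_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  tr <- cbind(subject_id = schedule$subject_id, schedule$trials)
  data.table::fwrite(tr, path, sep = "\t")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  tr <- as.data.frame(data.table::fread(path, sep = "\t"))
  required <- c("subject_id", "block", "index_in_block", "stimulus",
                "pitch_hz", "isi_ms", "onset_ms", "manipulation_phase",
                "block_direction")
  missing <- setdiff(required, names(tr))
  if (length(missing))
    stop("schedule file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(
    list(subject_id = tr$subject_id[1L], manipulation_after_block = 2L,
         trials = tr[setdiff(names(tr), "subject_id")]),
    class = "task_schedule"
  )
}
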