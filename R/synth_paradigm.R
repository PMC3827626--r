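# Paradigm and behavior simulation: a blocked audiovisual emotion-rating
# session with jittered inter-block pauses and a delayed-response trial
# structure.

# Evaluate expr with a private RNG state seeded by `seed`; the caller's
# RNG stream is untouched, so generators are deterministic and composable.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

EMO3 <- c("angry", "happy", "neutral")

#' Paradigm specification
#'
#' Defaults are the full session: 32 blocks (8 auditory, 8 visual, 16
#' audiovisual) of 12 trials each (384 trials: 96/96/192), inter-block
#' pauses jittered in 19-21 s, trials of 1-1.2 s stimulus + 1 s decision +
#' 1 s response.
#'
#' @param n_auditory,n_visual,n_audiovisual block counts per modality.
#' @param trials_per_block trials in every block.
#' @param pause_jitter_s inter-block pause interval (s).
#' @param stim_dur_s stimulus duration interval (s).
#' @param decision_dur_s,response_dur_s fixed phase durations (s).
#' @param lead_in_s,lead_out_s scanner time before the first and after the
#'   last block (s).
#' @param timing_uncertainty_mean_ms mean of the exponential presentation
#'   uncertainty attached to each stimulus marker.
#' @param seed RNG seed for ordering and jitter.
#' @return a `paradigm_spec` list.
#' @export
paradigm_spec <- function(n_auditory = 8, n_visual = 8, n_audiovisual = 16,
                          trials_per_block = 12,
                          pause_jitter_s = c(19, 21),
                          stim_dur_s = c(1, 1.2),
                          decision_dur_s = 1, response_dur_s = 1,
                          lead_in_s = 10, lead_out_s = 10,
                          timing_uncertainty_mean_ms = 2,
                          seed = 1) {
  if (trials_per_block %% 3 != 0)
    stop("trials_per_block must be divisible by 3 to balance emotions")
  structure(list(n_auditory = n_auditory, n_visual = n_visual,
                 n_audiovisual = n_audiovisual,
                 trials_per_block = trials_per_block,
                 pause_jitter_s = pause_jitter_s, stim_dur_s = stim_dur_s,
                 decision_dur_s = decision_dur_s,
                 response_dur_s = response_dur_s,
                 lead_in_s = lead_in_s, lead_out_s = lead_out_s,
                 timing_uncertainty_mean_ms = timing_uncertainty_mean_ms,
                 seed = seed),
            class = "paradigm_spec")
}

balanced_emotions <- function(k) sample(rep(EMO3, length.out = k))

#' Generate the pseudo-randomized session paradigm
#'
#' @param spec a [paradigm_spec()].
#' @param sampling_rate_hz rate on which marker onsets are expressed.
#' @return list with `markers` (stimulus markers), `trials` (a
#'   `trial_table`), `blocks` (block order and timing) and
#'   `total_duration_s`.
#' @export
build_paradigm <- function(spec = paradigm_spec(), sampling_rate_hz = 500) {
  with_seed(spec$seed, {
    blocks <- sample(c(rep("auditory", spec$n_auditory),
                       rep("visual", spec$n_visual),
                       rep("audiovisual", spec$n_audiovisual)))
    tpb <- spec$trials_per_block
    t <- spec$lead_in_s
    rows <- vector("list", length(blocks) * tpb)
    block_tab <- data.frame(block = seq_along(blocks), modality = blocks,
                            onset_s = NA_real_, pause_after_s = NA_real_)
    trial_id <- 0L
    for (bi in seq_along(blocks)) {
      mod <- blocks[bi]
      block_tab$onset_s[bi] <- t
      if (mod == "audiovisual") {
        congr <- sample(rep(c("CON", "INC"), length.out = tpb))
        vemo <- balanced_emotions(tpb)
        aemo <- ifelse(congr == "CON", vemo,
                       vapply(vemo, function(e) sample(setdiff(EMO3, e), 1), ""))
      } else if (mod == "visual") {
        congr <- rep("n/a", tpb); vemo <- balanced_emotions(tpb)
        aemo <- rep("none", tpb)
      } else {
        congr <- rep("n/a", tpb); aemo <- balanced_emotions(tpb)
        vemo <- rep("none", tpb)
      }
      for (ti in seq_len(tpb)) {
        trial_id <- trial_id + 1L
        stim_dur <- round(stats::runif(1, spec$stim_dur_s[1],
                                       spec$stim_dur_s[2]), 2)
        rows[[trial_id]] <- data.frame(
          trial_id = trial_id, onset_s = t, stim_dur_s = stim_dur,
          modality = mod, visual_emotion = vemo[ti],
          auditory_emotion = aemo[ti], congruence = congr[ti],
          uncertainty_ms = round(stats::rexp(
            1, 1 / spec$timing_uncertainty_mean_ms), 1),
          stringsAsFactors = FALSE)
        t <- t + stim_dur + spec$decision_dur_s + spec$response_dur_s
      }
      if (bi < length(blocks)) {
        pause <- round(stats::runif(1, spec$pause_jitter_s[1],
                                    spec$pause_jitter_s[2]), 2)
        block_tab$pause_after_s[bi] <- pause
        t <- t + pause
      }
    }
    tab <- do.call(rbind, rows)
    total <- t + spec$lead_out_s
    markers <- new_markers(
      onset_sample = round(tab$onset_s * sampling_rate_hz),
      kind = "stimulus", modality = tab$modality,
      visual_emotion = tab$visual_emotion,
      auditory_emotion = tab$auditory_emotion,
      congruence = tab$congruence,
      uncertainty_ms = tab$uncertainty_ms,
      trial_id = tab$trial_id)
    trials <- trials_from_markers(markers)
    trials$stim_dur_s <- tab$stim_dur_s
    list(markers = markers, trials = trials, blocks = block_tab,
         total_duration_s = total, sampling_rate_hz = sampling_rate_hz)
  })
}

emotion_code <- function(emo) match(emo, EMO3)

#' Simulate behavioral responses
#'
#' Per-condition Bernoulli correctness at configured rates; incongruent
#' trials receive a face/voice/neither decision with configured
#' proportions (response code set to the visual emotion, the auditory
#' emotion, or the remaining one). A fraction of trials is omitted (no
#' response).
#'
#' @param paradigm result of [build_paradigm()].
#' @param accuracy named rates for `auditory`, `visual`, `con` trials.
#' @param inc_probs decision proportions `face`, `voice`, `neither`
#'   (normalized internally).
#' @param omission_rate probability that no response is given.
#' @param rt_range_s uniform response-time range within the response phase.
#' @param seed RNG seed.
#' @return the paradigm list with `trials` filled in (response_code,
#'   correctness, inc_decision) and response markers appended to
#'   `markers`.
#' @export
simulate_behavior <- function(paradigm,
                              accuracy = c(auditory = 0.708, visual = 0.938,
                                           con = 0.929),
                              inc_probs = c(face = 0.510, voice = 0.284,
                                            neither = 0.226),
                              omission_rate = 0.02,
                              rt_range_s = c(0.2, 0.8),
                              seed = 1) {
  inc_probs <- inc_probs / sum(inc_probs)
  tr <- paradigm$trials
  fs <- paradigm$sampling_rate_hz
  with_seed(seed + 1000L, {
    n <- nrow(tr)
    omitted <- stats::runif(n) < omission_rate
    rc <- integer(n); correct <- character(n); dec <- rep("n/a", n)
    for (i in seq_len(n)) {
      if (omitted[i]) {
        rc[i] <- NA_integer_; correct[i] <- "omitted"; next
      }
      mod <- tr$modality[i]
      if (mod == "audiovisual" && tr$congruence[i] == "INC") {
        d <- sample(names(inc_probs), 1, prob = inc_probs)
        dec[i] <- d
        rc[i] <- switch(d,
          face = emotion_code(tr$visual_emotion[i]),
          voice = emotion_code(tr$auditory_emotion[i]),
          neither = setdiff(1:3, c(emotion_code(tr$visual_emotion[i]),
                                   emotion_code(tr$auditory_emotion[i])))[1])
        correct[i] <- if (d == "face") "correct" else "incorrect"
      } else {
        true_code <- if (mod == "auditory")
          emotion_code(tr$auditory_emotion[i])
        else emotion_code(tr$visual_emotion[i])
        acc <- switch(mod, auditory = accuracy[["auditory"]],
                      visual = accuracy[["visual"]],
                      audiovisual = accuracy[["con"]])
        if (stats::runif(1) < acc) {
          rc[i] <- true_code; correct[i] <- "correct"
        } else {
          rc[i] <- sample(setdiff(1:3, true_code), 1)
          correct[i] <- "incorrect"
        }
      }
    }
    tr$response_code <- rc
    tr$correctness <- correct
    tr$inc_decision <- dec
    # response markers: stimulus onset + stimulus + decision + RT
    resp <- !omitted
    if (any(resp)) {
      rt <- stats::runif(sum(resp), rt_range_s[1], rt_range_s[2])
      onset <- tr$onset_sample[resp] +
        round((tr$stim_dur_s[resp] + 1 + rt) * fs)
      rm_mark <- new_markers(onset_sample = onset, kind = "response",
                             response_code = rc[resp],
                             trial_id = tr$trial_id[resp])
      paradigm$markers <- rbind(paradigm$markers, rm_mark)
      class(paradigm$markers) <- c("marker_table", "data.frame")
    }
    # keep stimulus markers' response codes in sync for downstream scoring
    sti <- paradigm$markers$kind == "stimulus"
    paradigm$markers$response_code[sti] <-
      rc[match(paradigm$markers$trial_id[sti], tr$trial_id)]
    paradigm$trials <- tr
    paradigm
  })
}

#' Behavioral summary table
#'
#' Per-modality percent-correct plus decision proportions for incongruent
#' trials (face / voice / neither), mirroring a standard decision table.
#'
#' @param trials a scored `trial_table`.
#' @return one-row `data.frame` of percentages.
#' @export
behavior_summary <- function(trials) {
  pct <- function(x) 100 * mean(x)
  aud <- trials$modality == "auditory" & trials$correctness != "omitted"
  vis <- trials$modality == "visual" & trials$correctness != "omitted"
  con <- trials$congruence == "CON" & trials$correctness != "omitted"
  inc <- trials$congruence == "INC" & trials$correctness != "omitted"
  data.frame(
    auditory_pct = pct(trials$correctness[aud] == "correct"),
    visual_pct = pct(trials$correctness[vis] == "correct"),
    congruent_pct = pct(trials$correctness[con] == "correct"),
    inc_face_pct = pct(trials$inc_decision[inc] == "face"),
    inc_voice_pct = pct(trials$inc_decision[inc] == "voice"),
    inc_neither_pct = pct(trials$inc_decision[inc] == "neither"),
    omitted_pct = pct(trials$correctness == "omitted"))
}
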