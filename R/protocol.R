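#' Trial sequence of a perseveration condition
#'
#' Each condition is six spoon presentations: four lateral training
#' trials (T1--T4) followed by two neutral midline trials (N1, N2).
#' The control condition trains the preferred hand (spoon on the
#' preferred side), the test condition trains the nonpreferred hand.
#'
#' @param name `"control"` or `"test"`.
#' @return Data frame with columns `label` (T1..T4, N1, N2) and
#'   `laterality` (`"preferred_side"`, `"nonpreferred_side"` or
#'   `"neutral"`).
#' @examples
#' build_condition("test")
#' @export
build_condition <- function(name) {
  if (!name %in% c("control", "test"))
    stop("unknown condition name: ", name)
  lat <- if (name == "control") "preferred_side" else "nonpreferred_side"
  data.frame(
    label = c("T1", "T2", "T3", "T4", "N1", "N2"),
    laterality = c(rep(lat, 4), "neutral", "neutral"),
    stringsAsFactors = FALSE
  )
}

#' Fresh motor-memory state
#'
#' The memory trace is an accumulating input: after every trial the
#' site of the selected limb gains `increment`. It is zeroed before
#' and between conditions. By default the trace is perfectly
#' retained within a condition (`decay = 1`); `decay < 1` gives a
#' leaky trace, `m <- decay * m + increment`, provided as a
#' sensitivity variant (see the methods vignette).
#'
#' @param increment Memory step size per selection (default 1.2).
#' @param decay Retention factor applied to both sites' memory at
#'   each update, in `[0, 1]` (default 1 = no decay).
#' @return List with `m_p`, `m_np` (both 0), `increment`, `decay`.
#' @export
reset_memory <- function(increment = 1.2, decay = 1) {
  stopifnot(increment >= 0, decay >= 0, decay <= 1)
  list(m_p = 0, m_np = 0, increment = increment, decay = decay)
}

#' Add a selection to the memory trace
#'
#' @param memory A memory state from [reset_memory()] /
#'   `update_memory()`.
#' @param selected `"P"` or `"NP"`: the limb chosen on the trial just
#'   completed.
#' @return Updated memory state: both sites' memories are scaled by
#'   `memory$decay` (a no-op at the default 1), then the selected
#'   site's memory grows by `memory$increment`.
#' @export
update_memory <- function(memory, selected) {
  stopifnot(selected %in% c("P", "NP"))
  memory$m_p <- memory$decay * memory$m_p
  memory$m_np <- memory$decay * memory$m_np
  if (selected == "P") memory$m_p <- memory$m_p + memory$increment
  else memory$m_np <- memory$m_np + memory$increment
  memory
}

#' Total per-site drive for one trial
#'
#' Sensory input plus memory input. Lateral trials give the cued side
#' the strong input and the other side the weak input; neutral trials
#' give both sides the strong input.
#'
#' @param laterality `"preferred_side"`, `"nonpreferred_side"` or
#'   `"neutral"` (the `laterality` column of [build_condition()]).
#' @param scheme A [sensory_scheme()].
#' @param memory A memory state.
#' @return Named numeric vector `c(drive_p, drive_np)`.
#' @examples
#' trial_drive("nonpreferred_side", sensory_scheme(), reset_memory())
#' # drive_p = 1, drive_np = 6
#' @export
trial_drive <- function(laterality, scheme, memory) {
  sens <- switch(laterality,
    preferred_side = c(scheme$strong, scheme$weak),
    nonpreferred_side = c(scheme$weak, scheme$strong),
    neutral = c(scheme$strong, scheme$strong),
    stop("unknown laterality: ", laterality)
  )
  c(drive_p = sens[1] + memory$m_p, drive_np = sens[2] + memory$m_np)
}

#' Run one simulated participant through both conditions
#'
#' Runs the full protocol: the six trials of each condition in
#' `condition_order`, with the memory trace carried from trial to
#' trial within a condition and reset to zero between conditions.
#' Drives are fixed before each trial and constant during it. The
#' participant's noise comes from R's current RNG stream, consumed
#' trial by trial (preferred-site block, then nonpreferred-site
#' block), so a participant is exactly reproducible from a seed.
#'
#' @param params A [model_params()] object (e.g. an [age_preset()]).
#' @param scheme A [sensory_scheme()].
#' @param seed Optional integer; if given, `set.seed(seed)` is called
#'   first.
#' @param condition_order Character vector of the two condition names.
#' @param memory_increment Memory gain per selection (default 1.2).
#' @param memory_decay Memory retention factor per trial (default 1,
#'   no decay; see [reset_memory()]).
#' @return Object of class `limbselect_participant`: a list with
#'   `trials` (data frame: `condition`, `label`, `laterality`,
#'   `drive_p`, `drive_np`, `m_p`, `m_np` entering the trial,
#'   `selected`, `u_p_final`, `u_np_final`, `tie_broken`), `params`
#'   and `seed`.
#' @examples
#' r <- run_participant(age_preset("24mo", noise_strength = 0))
#' subset(r$trials, condition == "test")$selected # all "NP"
#' @export
run_participant <- function(params, scheme = sensory_scheme(),
                            seed = NULL,
                            condition_order = c("control", "test"),
                            memory_increment = 1.2,
                            memory_decay = 1) {
  validate_params(params)
  stopifnot(setequal(condition_order, c("control", "test")))
  if (!is.null(seed)) set.seed(seed)
  noisy <- params$noise_strength > 0
  rows <- vector("list", 12L)
  k <- 0L
  for (cond in condition_order) {
    trials <- build_condition(cond)
    memory <- reset_memory(memory_increment, memory_decay)
    for (i in seq_len(nrow(trials))) {
      drv <- trial_drive(trials$laterality[i], scheme, memory)
      noise_p <- noise_np <- NULL
      if (noisy) {
        noise_p <- matrix(stats::rnorm(params$n_steps), 1L)
        noise_np <- matrix(stats::rnorm(params$n_steps), 1L)
      }
      fin <- .integrate_trial(params$h, params$h, drv[["drive_p"]],
                              drv[["drive_np"]], params,
                              noise_p, noise_np)
      sel <- select_limb(fin$u_p, fin$u_np)
      k <- k + 1L
      rows[[k]] <- data.frame(
        condition = cond, label = trials$label[i],
        laterality = trials$laterality[i],
        drive_p = drv[["drive_p"]], drive_np = drv[["drive_np"]],
        m_p = memory$m_p, m_np = memory$m_np,
        selected = sel$selected,
        u_p_final = fin$u_p, u_np_final = fin$u_np,
        tie_broken = sel$tie_broken,
        stringsAsFactors = FALSE
      )
      memory <- update_memory(memory, sel$selected)
    }
  }
  structure(list(trials = do.call(rbind, rows), params = params,
                 seed = seed,
                 age_group = attr(params, "age_group")),
            class = "limbselect_participant")
}
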