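#' Agent policies for the session simulator
#'
#' Each simulated participant is an agent with a per-game skill profile
#' and a time-allocation policy:
#' * `"explore_then_exploit"` samples unplayed games until the
#'   exploration budget is spent, then repeatedly plays whichever game
#'   has shown the best experienced ticket rate; `choice_accuracy` is
#'   the probability of actually picking that best-known game at each
#'   decision (lapses pick uniformly), which is how the cohort
#'   generator injects graded decision-selection ability.
#' * `"uniform_random_switcher"` picks the next game uniformly at
#'   random every play — the low-decision-quality reference.
#' * `"sticky_first_game"` picks one (uncapped) game and never leaves.
#' * `"oracle"` always plays the game with the highest true current
#'   expected rate (skill x base rate x remaining yield).
#' Switching costs `switch_cost_s` travel seconds, including the walk
#' from the lobby to the first machine.
#'
#' @param policy_kind one of the four kinds above.
#' @param skill_vector per-game multipliers (> 0) on the catalog base
#'   rates; a scalar is recycled to all games.
#' @param exploration_budget_s seconds reserved for sampling unplayed
#'   games (explore-then-exploit only).
#' @param switch_cost_s travel seconds per switch.
#' @param choice_accuracy probability in (0, 1\] of choosing the
#'   best-known game during exploitation.
#' @param perseveration probability in \[0, 1\] that a lapse stays put
#'   in the current game (the failure-to-switch error mode) rather than
#'   wandering to a random machine.
#' @return An `agent_policy` list.
#' @export
agent_policy <- function(policy_kind = c("explore_then_exploit",
                                         "uniform_random_switcher",
                                         "sticky_first_game", "oracle"),
                         skill_vector = 1,
                         exploration_budget_s = 900,
                         switch_cost_s = 8,
                         choice_accuracy = 1,
                         perseveration = 0.5) {
  policy_kind <- match.arg(policy_kind)
  if (any(skill_vector <= 0)) stop("skill multipliers must be > 0")
  if (switch_cost_s < 0) stop("switch_cost_s must be >= 0")
  if (choice_accuracy <= 0 || choice_accuracy > 1) {
    stop("choice_accuracy must lie in (0, 1]")
  }
  if (perseveration < 0 || perseveration > 1) {
    stop("perseveration must lie in [0, 1]")
  }
  structure(list(policy_kind = policy_kind,
                 skill_vector = skill_vector,
                 exploration_budget_s = exploration_budget_s,
                 switch_cost_s = switch_cost_s,
                 choice_accuracy = choice_accuracy,
                 perseveration = perseveration),
            class = "agent_policy")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

choose_next <- function(policy, cat, plays, my_tickets, my_seconds, t,
                        current = NA_integer_) {
  avail <- which(plays < cat$max_plays)
  if (length(avail) == 0L) return(NA_integer_)
  pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  switch(policy$policy_kind,
    sticky_first_game = {
      played <- which(plays > 0L)
      if (length(played) > 0L) return(played[1L])
      pick1(which(!is.finite(cat$max_plays)))
    },
    uniform_random_switcher = pick1(avail),
    oracle = {
      rate <- policy$skill_vector * cat$base_rate * cat$yield_decay^plays
      cands <- avail[rate[avail] == max(rate[avail])]
      pick1(cands)
    },
    explore_then_exploit = {
      unplayed <- avail[plays[avail] == 0L]
      if (t < policy$exploration_budget_s && length(unplayed) > 0L) {
        return(pick1(unplayed))
      }
      if (stats::runif(1L) > policy$choice_accuracy) {
        # lapse: perseverate in the current game (the characteristic
        # failure-to-switch the score is built to detect) or wander to
        # a random machine, per the policy's perseveration tendency
        if (stats::runif(1L) < policy$perseveration &&
            !is.na(current) && current %in% avail) {
          return(current)
        }
        return(pick1(avail))
      }
      obs <- my_tickets / my_seconds            # NA for unplayed
      if (all(is.na(obs))) return(pick1(avail))
      obs[is.na(obs)] <- mean(obs, na.rm = TRUE)
      cands <- avail[obs[avail] == max(obs[avail])]
      pick1(cands)
    }
  )
}

#' Simulate one arcade session
#'
#' Plays out an 1800-second session under an [agent_policy()]: the
#' agent repeatedly picks a machine, pays the travel cost, and plays
#' for roughly the game's typical duration; each play emits
#' `round(skill x base_rate x yield_decay^plays x duration x noise)`
#' tickets with log-normal multiplicative noise (sdlog 0.3). Play-count
#' caps and yield decay are honored, the final play is truncated at the
#' budget, and all randomness flows through `seed`, so the same seed
#' reproduces the log exactly. Generated logs are already clean:
#' [clean_session_log()] applies zero corrections to them.
#'
#' @param catalog a [game_catalog()].
#' @param policy an [agent_policy()].
#' @param seed integer seed (NULL inherits the current RNG state).
#' @param participant_id id stored in the log.
#' @param duration_s session budget in seconds.
#' @return A [session_log()].
#' @export
simulate_session <- function(catalog, policy, seed = NULL,
                             participant_id = "sim", duration_s = 1800) {
  stopifnot(inherits(policy, "agent_policy"))
  g <- nrow(catalog)
  skill <- rep_len(policy$skill_vector, g)
  with_seed(seed, {
    plays <- integer(g)
    my_tickets <- rep(0, g); my_seconds <- rep(0, g)
    segs <- vector("list", 64L)
    nseg <- 0L
    t <- 0
    current <- NA_integer_
    repeat {
      nxt <- choose_next(policy, catalog, plays, my_tickets, my_seconds, t,
                         current = current)
      if (is.na(nxt)) break
      if (is.na(current) || nxt != current) t <- t + policy$switch_cost_s
      if (t >= duration_s) break
      dur <- round(stats::rlnorm(1L, log(catalog$play_duration[nxt]), 0.25))
      dur <- max(10, dur)
      dur <- min(dur, duration_s - t)
      rate <- skill[nxt] * catalog$base_rate[nxt] * catalog$yield_decay[nxt]^plays[nxt]
      tickets <- max(0, round(rate * dur * stats::rlnorm(1L, 0, 0.3)))
      nseg <- nseg + 1L
      if (nseg > length(segs)) segs <- c(segs, vector("list", length(segs)))
      segs[[nseg]] <- c(t, t + dur, nxt, tickets)
      plays[nxt] <- plays[nxt] + 1L
      my_tickets[nxt] <- my_tickets[nxt] + tickets
      my_seconds[nxt] <- my_seconds[nxt] + dur
      current <- nxt
      t <- t + dur
      if (t >= duration_s) break
    }
    m <- do.call(rbind, segs[seq_len(nseg)])
    segments <- if (nseg == 0L) {
      data.frame(game_id = character(), start_s = numeric(),
                 end_s = numeric(), tickets = numeric())
    } else {
      data.frame(game_id = catalog$game_id[m[, 3L]],
                 start_s = m[, 1L], end_s = m[, 2L], tickets = m[, 4L],
                 stringsAsFactors = FALSE)
    }
    session_log(participant_id, segments, duration_s = duration_s)
  })
}

#' Cohort specification
#'
#' Describes a synthetic study sample: `n` participants whose six
#' latent traits — game skill, selection (decision) ability, age, and
#' the CRT / AOMTB / NCS questionnaire propensities — are drawn from a
#' standard multivariate normal with the given correlation matrix. The
#' default correlation structure injects the qualitative relations the
#' analyses look for: skill and selection ability are moderately
#' related, skill tracks cognitive reflection and declines with age,
#' and the questionnaire traits are mildly intercorrelated.
#'
#' @param n_participants cohort size (>= 2).
#' @param correlation 6x6 positive semi-definite trait correlation
#'   matrix with dimnames among (skill, selection, age, crt, aomtb,
#'   ncs); default [default_trait_correlation()].
#' @param seed integer seed for all cohort-level randomness.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants, correlation = default_trait_correlation(),
                        seed = 1L) {
  if (n_participants < 2L) stop("n_participants must be >= 2")
  traits <- c("skill", "selection", "age", "crt", "aomtb", "ncs")
  if (!identical(dim(correlation), c(6L, 6L)) ||
      !identical(rownames(correlation), traits)) {
    stop("correlation must be a 6x6 matrix with dimnames ",
         paste(traits, collapse = ", "))
  }
  if (any(abs(correlation - t(correlation)) > 1e-8)) stop("correlation must be symmetric")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation must be positive semi-definite")
  structure(list(n_participants = as.integer(n_participants),
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_trait_correlation <- function() {
  traits <- c("skill", "selection", "age", "crt", "aomtb", "ncs")
  m <- diag(6)
  dimnames(m) <- list(traits, traits)
  set_pair <- function(m, a, b, v) { m[a, b] <- m[b, a] <- v; m }
  m <- set_pair(m, "skill", "selection", 0.35)
  m <- set_pair(m, "skill", "crt", 0.30)
  m <- set_pair(m, "skill", "age", -0.25)
  m <- set_pair(m, "selection", "crt", 0.10)
  m <- set_pair(m, "crt", "ncs", 0.25)
  m <- set_pair(m, "aomtb", "ncs", 0.30)
  m
}

# standard-normal draws with the requested correlation (via Cholesky
# with a PSD-safe eigen fallback)
draw_traits <- function(n, correlation) {
  z <- matrix(stats::rnorm(n * ncol(correlation)), n)
  ch <- tryCatch(chol(correlation), error = function(e) {
    ev <- eigen(correlation, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    chol(ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors) + diag(1e-10, ncol(correlation)))
  })
  out <- z %*% ch
  colnames(out) <- colnames(correlation)
  out
}

#' Simulate a study cohort
#'
#' Draws latent traits per [cohort_spec()], maps them to agent policies
#' and questionnaire item responses, and simulates one session per
#' participant. Trait-to-observable mappings (documented in the methods
#' vignette): skill multiplier `exp(0.15 z)`; exploitation choice
#' accuracy `plogis(-2 + 2 z)` with lapse perseveration
#' `plogis(1.5 - 1.5 z)` in the selection trait; age `round(23 + 5.5 z)`
#' clipped to 18-65;
#' CRT items Bernoulli with logistic difficulty offsets; AOMTB / NCS
#' Likert items as noisy discretizations of the trait, with the
#' [default_reverse_items()] stored in reversed form so that scoring
#' (which un-reverses them) recovers the trait.
#'
#' @param spec a [cohort_spec()].
#' @param catalog a [game_catalog()].
#' @return A `cohort` list: `logs` (list of [session_log()]),
#'   `questionnaires` (list with item-response matrices `crt`, `aomtb`,
#'   `ncs`), `age` (integer vector), `traits` (latent draw matrix),
#'   `seed`.
#' @export
simulate_cohort <- function(spec, catalog = default_catalog()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(spec$seed, {
    z <- draw_traits(n, spec$correlation)
    session_seeds <- sample.int(.Machine$integer.max - 1L, n)
    age <- pmin(pmax(round(23 + 5.5 * z[, "age"]), 18L), 65L)

    crt_difficulty <- c(0.3, -0.2, -0.6, -0.9, -1.2, -1.6, -2.0)
    crt_items <- matrix(0L, n, 7L)
    for (i in 1:7) {
      crt_items[, i] <- as.integer(
        stats::runif(n) < stats::plogis(z[, "crt"] + crt_difficulty[i]))
    }
    rev_sets <- default_reverse_items()
    aomtb_items <- matrix(0L, n, 11L)
    for (i in 1:11) {
      resp <- pmin(pmax(round(4.85 + 0.55 * z[, "aomtb"] + stats::rnorm(n, 0, 0.8)), 1L), 6L)
      if (i %in% rev_sets$aomtb) resp <- 7L - resp
      aomtb_items[, i] <- resp
    }
    ncs_items <- matrix(0L, n, 18L)
    for (i in 1:18) {
      resp <- pmin(pmax(round(0.34 + 0.50 * z[, "ncs"] + stats::rnorm(n, 0, 0.9)), -2L), 2L)
      if (i %in% rev_sets$ncs) resp <- -resp
      ncs_items[, i] <- resp
    }

    aptitude_jitter <- matrix(stats::rnorm(n * nrow(catalog), 0, 0.15), n)
    logs <- vector("list", n)
    for (i in seq_len(n)) {
      pol <- agent_policy(
        "explore_then_exploit",
        skill_vector = exp(0.15 * z[i, "skill"] + aptitude_jitter[i, ]),
        exploration_budget_s = 900,
        switch_cost_s = 8,
        choice_accuracy = stats::plogis(-2 + 2 * z[i, "selection"]),
        perseveration = stats::plogis(1.5 - 1.5 * z[i, "selection"])
      )
      logs[[i]] <- simulate_session(catalog, pol, seed = session_seeds[i],
                                    participant_id = sprintf("sim%04d", i))
    }
    structure(list(logs = logs,
                   questionnaires = list(crt = crt_items, aomtb = aomtb_items,
                                         ncs = ncs_items),
                   age = age, traits = z, seed = spec$seed),
              class = "cohort")
  })
}

#' Score a simulated cohort into a participant table
#'
#' Runs the standard scoring pipeline over a [simulate_cohort()] result:
#' session measures plus questionnaire totals (reverse-keyed items per
#' [default_reverse_items()]) and age.
#'
#' @param cohort a `cohort`.
#' @param catalog a [game_catalog()].
#' @param normalization passed to [dmx_score()].
#' @return data.frame with one row per participant: participant_id,
#'   age, tickets, dmx, games, switches, crt, aomtb, ncs.
#' @export
score_cohort <- function(cohort, catalog = default_catalog(),
                         normalization = "rank") {
  tab <- score_sessions(cohort$logs, catalog = catalog,
                        normalization = normalization)
  rev_sets <- default_reverse_items()
  n <- length(cohort$logs)
  tab$age <- cohort$age
  tab$crt <- vapply(seq_len(n), function(i)
    score_crt(cohort$questionnaires$crt[i, ]), integer(1L))
  tab$aomtb <- vapply(seq_len(n), function(i)
    score_aomtb(cohort$questionnaires$aomtb[i, ], rev_sets$aomtb), integer(1L))
  tab$ncs <- vapply(seq_len(n), function(i)
    score_ncs(cohort$questionnaires$ncs[i, ], rev_sets$ncs), integer(1L))
  tab[c("participant_id", "age", "tickets", "dmx", "games", "switches",
        "crt", "aomtb", "ncs")]
}
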