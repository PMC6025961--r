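# Agent-based two-reporter state-switching simulator.
#
# Model, in brief: cells elongate exponentially and divide at a threshold
# length; each cell carries two independent binary expression states
# (sucC+/competent, alsS+/acetoin-producing) with memoryless entry/exit;
# alsS entry is acetate-induced through a Hill function; growth of every
# cell is slowed multiplicatively by acetate toxicity K_tox/(K_tox + A);
# sucC+ cells secrete acetate, alsS+ cells consume it and produce acetoin.
# Reporters are stable proteins: production minus growth dilution, no
# degradation, concentration-conserving partition at division.

# alsS activation rate at a given ambient acetate (1/min)
.hill_on_rate <- function(acetate, p) {
  p$k0_alsS + p$kmax_alsS * acetate^p$h_alsS /
    (p$K_alsS^p$h_alsS + acetate^p$h_alsS)
}

# multiplicative growth slow-down from acetate toxicity
.tox_factor <- function(acetate, K_tox) {
  if (!is.finite(K_tox)) return(1)
  K_tox / (K_tox + acetate)
}

# exact update of a stable reporter: dF/dt = beta - r F over one step
.reporter_step <- function(f, beta, r, dt) {
  out <- f + beta * dt                      # r == 0 limit
  pos <- r > 0
  if (any(pos)) {
    ss <- beta[pos] / r[pos]
    out[pos] <- ss + (f[pos] - ss) * exp(-r[pos] * dt)
  }
  out
}

# Bernoulli switching draws from exponential waiting times over dt
.switch_draw <- function(current, k_on, k_off, dt, n) {
  turn_on  <- !current & (stats::runif(n) < 1 - exp(-k_on * dt))
  turn_off <-  current & (stats::runif(n) < 1 - exp(-k_off * dt))
  (current | turn_on) & !turn_off
}

# division-site placement fraction, clamped away from degenerate splits
.site_fraction <- function(n, div_cv) {
  if (div_cv <= 0) return(rep(0.5, n))
  pmin(pmax(stats::rnorm(n, 0.5, 0.5 * div_cv), 0.25), 0.75)
}

# per-cell multiplicative growth-rate factor, mean 1
.rate_factor <- function(n, r_cv) {
  if (r_cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, -r_cv^2 / 2, r_cv))
}

# co-utilization of the two preferred carbon sources: glucose carries a
# fixed share of the carbon flux while it lasts (it is the smaller pool,
# so it is exhausted around mid-exponential phase, closing the
# competence window), after which malate alone sustains growth through
# the acetate-reabsorption phase; shortfalls spill between pools
.consume_carbon <- function(glu, mal, need, glucose_share = 0.85) {
  clamped <- 0L
  if (need > 0) {
    dg <- min(glu, glucose_share * need)
    dm <- min(mal, need - dg)
    dg <- min(glu, need - dm)
    if (dg + dm < need - 1e-12) clamped <- 1L
    glu <- glu - dg; mal <- mal - dm
  }
  c(glu, mal, clamped)
}

.state_penalty <- function(sucC, alsS, p) {
  ifelse(sucC, p$penalty_sucC, 1) * ifelse(alsS, p$penalty_alsS, 1)
}

# division length threshold with a relative tolerance so that exact
# deterministic doublings are not missed to floating-point rounding
.ready_to_divide <- function(L, L_div) {
  if (!is.finite(L_div)) return(rep(FALSE, length(L)))
  L >= L_div * (1 - 1e-9)
}

.lineage_cols <- c("cell_id", "parent_id", "channel_id", "frame", "t_min",
                   "length_um", "f_sucC", "f_alsS", "state_sucC",
                   "state_alsS", "fate")

#' Simulate a closed batch culture
#'
#' Runs the interaction model in a well-mixed closed compartment: a fixed
#' ensemble of tracked cells (constant-number Monte Carlo) represents the
#' population, while a scalar biomass grows at the ensemble-mean rate and
#' drives carbon consumption and metabolite exchange. sucC+ cells secrete
#' acetate while primary carbon (glucose + malate) lasts; accumulated
#' acetate induces the alsS+ state, whose cells consume acetate and
#' produce acetoin at `y_acetoin` mol per mol. Competence entry requires
#' active growth on glucose, which makes the sucC+ subpopulation transient.
#'
#' @param params a [switch_params()] object.
#' @param config a [scenario_config()] with `mode = "batch"`.
#' @return A list of class `metaswitch_batch` with elements
#'   `environment` (tibble: `t_min`, `biomass`, `glucose_mM`, `malate_mM`,
#'   `acetate_mM`, `acetoin_mM`, state fractions and cumulative acetate
#'   bookkeeping columns) and `snapshots` (long tibble of per-cell
#'   fluorescence per frame and reporter: `t_min`, `od`, `reporter`,
#'   `value`, `state_on`).
#' @examples
#' run <- simulate_batch(switch_params(),
#'                       scenario_config("batch", duration = 120,
#'                                       frame_interval = 30, seed = 1,
#'                                       n_sample = 50))
#' head(run$environment)
#' @export
simulate_batch <- function(params, config) {
  stopifnot(inherits(params, "switch_params"), inherits(config, "scenario_config"))
  if (config$mode != "batch") stop("config mode must be 'batch'", call. = FALSE)
  p <- .effective_params(params, config)
  set.seed(config$seed)

  n  <- config$n_sample
  nf <- as.integer(round(config$duration / config$frame_interval))
  dt <- config$frame_interval / config$substeps
  e0 <- config$initial_env
  B <- e0$biomass; glu <- e0$glucose; mal <- e0$malate
  ace <- e0$acetate; acn <- e0$acetoin
  cum_prod <- 0; cum_cons <- 0; n_clamped <- 0L

  if (n > 0) {
    rfac <- .rate_factor(n, p$r_cv)
    L <- if (is.finite(p$L_div)) p$L_div / 2 * 2^stats::runif(n) else rep(3, n)
    sucC <- rep(FALSE, n); alsS <- rep(FALSE, n)
    r0 <- p$r_base * rfac
    F_s <- if (p$r_base > 0) p$beta_off / r0 else rep(0, n)
    F_a <- F_s
  }

  env_rows <- vector("list", nf + 1L)
  snap_rows <- vector("list", nf + 1L)
  record <- function(fr) {
    t_now <- (fr - 1L) * config$frame_interval
    fs <- if (n > 0) mean(sucC) else 0
    fa <- if (n > 0) mean(alsS) else 0
    env_rows[[fr]] <<- data.frame(
      t_min = t_now, biomass = B, glucose_mM = glu, malate_mM = mal,
      acetate_mM = ace, acetoin_mM = acn,
      frac_sucC_on = fs, frac_alsS_on = fa,
      cum_acetate_produced = cum_prod, cum_acetate_consumed = cum_cons)
    if (n > 0)
      snap_rows[[fr]] <<- data.frame(
        t_min = t_now, od = B,
        reporter = rep(c("sucC", "alsS"), each = n),
        value = c(F_s, F_a),
        state_on = c(sucC, alsS))
  }

  record(1L)
  if (nf > 0) for (fr in seq_len(nf)) {
    for (s in seq_len(config$substeps)) {
      if (n > 0) {
        f_c <- (glu + mal) / (p$K_C + glu + mal)
        f_g <- glu / (p$K_C + glu)
        f_t <- .tox_factor(ace, p$K_tox)
        r_i <- p$r_base * rfac * .state_penalty(sucC, alsS, p) * f_c * f_t
        L <- L * exp(r_i * dt)
        gbar <- mean(exp(r_i * dt))
        B_new <- B * gbar
        need <- (B_new - B) / p$yield_od_per_mM
        cc <- .consume_carbon(glu, mal, need)
        glu <- cc[1]; mal <- cc[2]; n_clamped <- n_clamped + cc[3]
        B <- B_new
        frac_s <- mean(sucC); frac_a <- mean(alsS)
        prod <- (p$p_A * frac_s + p$p_A_basal) * B * f_c * dt
        cons <- min(p$c_A * frac_a * B * dt, ace + prod)
        ace <- ace + prod - cons
        cum_prod <- cum_prod + prod; cum_cons <- cum_cons + cons
        acn <- acn + p$y_acetoin * cons
        sucC <- .switch_draw(sucC, p$k_on_sucC * p$quorum * f_g,
                             p$k_off_sucC, dt, n)
        alsS <- .switch_draw(alsS, .hill_on_rate(ace, p), p$k_off_alsS, dt, n)
        # protein synthesis needs substrate: production scales with f_c,
        # so reporters freeze (exactly) once carbon is exhausted
        F_s <- .reporter_step(F_s, ifelse(sucC, p$beta_on, p$beta_off) * f_c, r_i, dt)
        F_a <- .reporter_step(F_a, ifelse(alsS, p$beta_on, p$beta_off) * f_c, r_i, dt)
        div <- .ready_to_divide(L, p$L_div)
        if (any(div)) {       # constant-number: keep one daughter at random
          f <- .site_fraction(sum(div), p$div_cv)
          L[div] <- L[div] * f
          rfac[div] <- .rate_factor(sum(div), p$r_cv)
        }
      }
    }
    record(fr + 1L)
  }

  out <- list(environment = tibble::as_tibble(do.call(rbind, env_rows)),
              snapshots = tibble::as_tibble(do.call(rbind, snap_rows)),
              params = p, config = config, n_clamped = n_clamped)
  class(out) <- "metaswitch_batch"
  out
}

#' Simulate mother-machine microfluidic growth channels
#'
#' Each dead-end channel retains the cell at its capped end (the "mother",
#' position 1); daughters push the queue toward the open end and cells
#' beyond the channel capacity are washed out. The environment is
#' chemostatic: acetate and quorum activity are fixed at
#' `config$media_condition` for the whole run, and carbon is replete.
#' State transitions are memoryless with exponential waiting times (the
#' alsS entry rate is evaluated at the fixed acetate level); initial
#' states are drawn from the stationary occupancy of each two-state
#' switch, as for cells loaded from a culture pre-adapted to the medium.
#'
#' @inheritParams simulate_batch
#' @param config a [scenario_config()] with `mode = "mother_machine"`.
#' @return A lineage table (tibble) with one row per cell per frame:
#'   `cell_id`, `parent_id`, `channel_id`, `frame`, `t_min`, `length_um`,
#'   `f_sucC`, `f_alsS`, `state_sucC`, `state_alsS`, `fate`
#'   (`live`/`divided`/`washed_out`).
#' @examples
#' lin <- simulate_mother_machine(
#'   switch_params(),
#'   scenario_config("mother_machine", duration = 240, seed = 1,
#'                   n_channels = 3, channel_capacity = 2))
#' table(lin$fate)
#' @export
simulate_mother_machine <- function(params, config) {
  stopifnot(inherits(params, "switch_params"), inherits(config, "scenario_config"))
  if (config$mode != "mother_machine")
    stop("config mode must be 'mother_machine'", call. = FALSE)
  p <- .effective_params(params, config)
  set.seed(config$seed)

  nch <- config$n_channels
  if (nch == 0L)
    return(tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.lineage_cols))),
      .lineage_cols)))
  cap <- config$channel_capacity
  nf <- as.integer(round(config$duration / config$frame_interval))
  dt <- config$frame_interval / config$substeps
  A   <- config$media_condition$acetate
  quo <- config$media_condition$quorum
  k_on_s <- p$k_on_sucC * p$quorum * quo
  k_on_a <- .hill_on_rate(A, p)
  f_t <- .tox_factor(A, p$K_tox)

  n <- nch
  id <- seq_len(n); parent <- rep(NA_integer_, n)
  channel <- seq_len(nch); pos <- rep(1L, n)
  next_id <- n + 1L
  rfac <- .rate_factor(n, p$r_cv)
  L <- if (is.finite(p$L_div)) p$L_div / 2 * 2^stats::runif(n) else rep(3, n)
  occ_s <- if (k_on_s + p$k_off_sucC > 0) k_on_s / (k_on_s + p$k_off_sucC) else 0
  occ_a <- if (k_on_a + p$k_off_alsS > 0) k_on_a / (k_on_a + p$k_off_alsS) else 0
  sucC <- stats::runif(n) < occ_s
  alsS <- stats::runif(n) < occ_a
  r_i <- p$r_base * rfac * .state_penalty(sucC, alsS, p) * f_t
  F_s <- ifelse(r_i > 0, ifelse(sucC, p$beta_on, p$beta_off) / r_i, 0)
  F_a <- ifelse(r_i > 0, ifelse(alsS, p$beta_on, p$beta_off) / r_i, 0)

  washed <- integer(0)
  rec <- vector("list", nf + 1L)
  record <- function(fr) {
    m <- length(id)
    noise <- if (p$length_noise_cv > 0)
      exp(stats::rnorm(m, 0, p$length_noise_cv)) else 1
    rec[[fr]] <<- data.frame(
      cell_id = id, parent_id = parent, channel_id = channel,
      frame = fr, t_min = (fr - 1L) * config$frame_interval,
      length_um = L * noise, f_sucC = F_s, f_alsS = F_a,
      state_sucC = as.integer(sucC), state_alsS = as.integer(alsS))
  }

  record(1L)
  if (nf > 0) for (fr in seq_len(nf)) {
    for (s in seq_len(config$substeps)) {
      t_now <- (fr - 1L) * config$frame_interval + s * dt
      r_i <- p$r_base * rfac * .state_penalty(sucC, alsS, p) * f_t
      L <- L * exp(r_i * dt)
      n_now <- length(id)
      sucC <- .switch_draw(sucC, k_on_s, p$k_off_sucC, dt, n_now)
      alsS <- .switch_draw(alsS, k_on_a, p$k_off_alsS, dt, n_now)
      F_s <- .reporter_step(F_s, ifelse(sucC, p$beta_on, p$beta_off), r_i, dt)
      F_a <- .reporter_step(F_a, ifelse(alsS, p$beta_on, p$beta_off), r_i, dt)
      dividers <- which(.ready_to_divide(L, p$L_div))
      for (i in dividers) {
        f <- .site_fraction(1L, p$div_cv)
        ch <- channel[i]; p0 <- pos[i]
        shift <- channel == ch & pos > p0
        pos[shift] <- pos[shift] + 1L
        # old-pole daughter keeps the slot nearer the cap
        id      <- c(id, next_id, next_id + 1L)
        parent  <- c(parent, id[i], id[i])
        channel <- c(channel, ch, ch)
        pos     <- c(pos, p0, p0 + 1L)
        L       <- c(L, L[i] * f, L[i] * (1 - f))
        sucC    <- c(sucC, sucC[i], sucC[i])
        alsS    <- c(alsS, alsS[i], alsS[i])
        F_s     <- c(F_s, F_s[i], F_s[i])   # concentration-conserving
        F_a     <- c(F_a, F_a[i], F_a[i])
        rfac    <- c(rfac, .rate_factor(2L, p$r_cv))
        next_id <- next_id + 2L
        keep <- seq_along(id) != i
        id <- id[keep]; parent <- parent[keep]; channel <- channel[keep]
        pos <- pos[keep]; L <- L[keep]; sucC <- sucC[keep]; alsS <- alsS[keep]
        F_s <- F_s[keep]; F_a <- F_a[keep]; rfac <- rfac[keep]
      }
      out <- pos > cap
      if (any(out)) {
        washed <- c(washed, id[out])
        keep <- !out
        id <- id[keep]; parent <- parent[keep]; channel <- channel[keep]
        pos <- pos[keep]; L <- L[keep]; sucC <- sucC[keep]; alsS <- alsS[keep]
        F_s <- F_s[keep]; F_a <- F_a[keep]; rfac <- rfac[keep]
      }
    }
    record(fr + 1L)
  }

  .finish_lineage(do.call(rbind, rec), washed)
}

# assign fates from parent links and the washout log, return tibble
.finish_lineage <- function(df, washed) {
  df <- df[order(df$cell_id, df$frame), , drop = FALSE]
  last <- !duplicated(df$cell_id, fromLast = TRUE)
  fate <- rep("live", nrow(df))
  divided_ids <- unique(df$parent_id[!is.na(df$parent_id)])
  fate[last & df$cell_id %in% divided_ids] <- "divided"
  fate[last & df$cell_id %in% washed] <- "washed_out"
  df$fate <- fate
  tibble::as_tibble(df[order(df$frame, df$channel_id, df$cell_id), ])
}

#' Simulate a microcolony on an agarose pad
#'
#' A closed shared environment (default: glucose medium plus 20 mM
#' acetate, the concentration of mid-exponential batch phase) is updated
#' from the live cells each step; the full genealogy is retained, with
#' every division producing exactly two recorded daughters. Growth of all
#' cells is slowed by acetate toxicity and recovers as alsS+ cells deplete
#' acetate into acetoin.
#'
#' @inheritParams simulate_batch
#' @param config a [scenario_config()] with `mode = "pad"`. The pad
#'   default environment is taken from `config$initial_env` with malate
#'   absent unless set explicitly.
#' @return A list of class `metaswitch_pad` with elements `lineage`
#'   (tibble in the same dialect as [simulate_mother_machine()], with
#'   `channel_id = NA`) and `environment` (as in [simulate_batch()]).
#' @examples
#' run <- simulate_pad(switch_params(),
#'                     scenario_config("pad", duration = 120, seed = 1,
#'                                     n_founders = 2))
#' nrow(run$lineage)
#' @export
simulate_pad <- function(params, config) {
  stopifnot(inherits(params, "switch_params"), inherits(config, "scenario_config"))
  if (config$mode != "pad") stop("config mode must be 'pad'", call. = FALSE)
  p <- .effective_params(params, config)
  set.seed(config$seed)

  nf <- as.integer(round(config$duration / config$frame_interval))
  dt <- config$frame_interval / config$substeps
  quo <- config$media_condition$quorum
  e0 <- config$initial_env
  glu <- e0$glucose; mal <- e0$malate
  ace <- e0$acetate; acn <- e0$acetoin
  cum_prod <- 0; cum_cons <- 0; n_clamped <- 0L
  # biomass in OD-equivalents: od_per_cell per newborn-length unit, so it
  # varies smoothly as cells elongate and is conserved at division
  L_ref <- if (is.finite(p$L_div)) p$L_div / 2 else 3

  n <- config$n_founders
  stopifnot(n >= 1L)
  id <- seq_len(n); parent <- rep(NA_integer_, n)
  birth_t <- rep(0, n); next_id <- n + 1L
  rfac <- .rate_factor(n, p$r_cv)
  L <- if (is.finite(p$L_div)) p$L_div / 2 * 2^stats::runif(n) else rep(3, n)
  sucC <- rep(FALSE, n); alsS <- rep(FALSE, n)
  r00 <- p$r_base * rfac * (glu + mal) / (p$K_C + glu + mal) *
    .tox_factor(ace, p$K_tox)
  F_s <- ifelse(r00 > 0, p$beta_off / r00, 0)
  F_a <- F_s

  biomass <- function() config$od_per_cell * sum(L) / L_ref

  env_rows <- vector("list", nf + 1L)
  rec <- vector("list", nf + 1L)
  record <- function(fr) {
    m <- length(id)
    noise <- if (p$length_noise_cv > 0)
      exp(stats::rnorm(m, 0, p$length_noise_cv)) else 1
    rec[[fr]] <<- data.frame(
      cell_id = id, parent_id = parent, channel_id = NA_integer_,
      frame = fr, t_min = (fr - 1L) * config$frame_interval,
      length_um = L * noise, f_sucC = F_s, f_alsS = F_a,
      state_sucC = as.integer(sucC), state_alsS = as.integer(alsS))
    env_rows[[fr]] <<- data.frame(
      t_min = (fr - 1L) * config$frame_interval, biomass = biomass(),
      glucose_mM = glu, malate_mM = mal, acetate_mM = ace, acetoin_mM = acn,
      frac_sucC_on = mean(sucC), frac_alsS_on = mean(alsS),
      cum_acetate_produced = cum_prod, cum_acetate_consumed = cum_cons)
  }

  record(1L)
  if (nf > 0) for (fr in seq_len(nf)) {
    for (s in seq_len(config$substeps)) {
      f_c <- (glu + mal) / (p$K_C + glu + mal)
      f_g <- glu / (p$K_C + glu)
      f_t <- .tox_factor(ace, p$K_tox)
      r_i <- p$r_base * rfac * .state_penalty(sucC, alsS, p) * f_c * f_t
      # the agarose bulk acts as a carbon reservoir (glucose resupplied
      # by diffusion, pools held constant); secreted metabolites stay
      # local to the colony and are treated as a closed pool
      L <- L * exp(r_i * dt)
      B <- biomass()
      B_s <- config$od_per_cell * sum(L[sucC]) / L_ref
      B_a <- config$od_per_cell * sum(L[alsS]) / L_ref
      prod <- (p$p_A * B_s + p$p_A_basal * B) * f_c * dt
      cons <- min(p$c_A * B_a * dt, ace + prod)
      ace <- ace + prod - cons
      cum_prod <- cum_prod + prod; cum_cons <- cum_cons + cons
      acn <- acn + p$y_acetoin * cons
      n_now <- length(id)
      # competence entry also needs the quorum/conditioned-media signal;
      # an isolated microcolony on fresh pad medium has essentially none
      sucC <- .switch_draw(sucC, p$k_on_sucC * p$quorum * quo * f_g,
                           p$k_off_sucC, dt, n_now)
      alsS <- .switch_draw(alsS, .hill_on_rate(ace, p), p$k_off_alsS, dt, n_now)
      F_s <- .reporter_step(F_s, ifelse(sucC, p$beta_on, p$beta_off) * f_c, r_i, dt)
      F_a <- .reporter_step(F_a, ifelse(alsS, p$beta_on, p$beta_off) * f_c, r_i, dt)
      dividers <- which(.ready_to_divide(L, p$L_div))
      if (length(dividers)) {
        nd <- length(dividers)
        f <- .site_fraction(nd, p$div_cv)
        id      <- c(id, next_id + seq_len(2 * nd) - 1L)
        parent  <- c(parent, id[dividers], id[dividers])
        L       <- c(L, L[dividers] * f, L[dividers] * (1 - f))
        sucC    <- c(sucC, sucC[dividers], sucC[dividers])
        alsS    <- c(alsS, alsS[dividers], alsS[dividers])
        F_s     <- c(F_s, F_s[dividers], F_s[dividers])
        F_a     <- c(F_a, F_a[dividers], F_a[dividers])
        rfac    <- c(rfac, .rate_factor(2 * nd, p$r_cv))
        next_id <- next_id + 2L * nd
        keep <- !(seq_along(id) %in% dividers)
        id <- id[keep]; parent <- parent[keep]; L <- L[keep]
        sucC <- sucC[keep]; alsS <- alsS[keep]
        F_s <- F_s[keep]; F_a <- F_a[keep]; rfac <- rfac[keep]
      }
    }
    record(fr + 1L)
  }

  out <- list(lineage = .finish_lineage(do.call(rbind, rec), integer(0)),
              environment = tibble::as_tibble(do.call(rbind, env_rows)),
              params = p, config = config, n_clamped = n_clamped)
  class(out) <- "metaswitch_pad"
  out
}

#' Update a single cell's reporters over a time step
#'
#' Stable-reporter dynamics: fluorescence concentration follows
#' production (`beta_on` in the on state, `beta_off` otherwise) minus
#' dilution by growth; there is no degradation. The update is the exact
#' solution of `dF/dt = beta - r F`, so after a switch F relaxes toward
#' `beta/r` with e-folding time `1/r`. At division both daughters inherit
#' the mother's concentration unchanged.
#'
#' @param state a named list with logical `sucC_state`, `alsS_state` and
#'   numeric `F_sucC`, `F_alsS` (a `CellState`).
#' @param dt time step (min), > 0.
#' @param params a [switch_params()] object.
#' @param growth_rate the cell's current specific growth rate (1/min);
#'   defaults to `r_base` times the state growth penalties.
#' @return the updated state list.
#' @examples
#' st <- list(sucC_state = TRUE, alsS_state = FALSE, F_sucC = 0, F_alsS = 0)
#' reporter_update(st, dt = 600, params = switch_params())$F_sucC
#' @export
reporter_update <- function(state, dt, params, growth_rate = NULL) {
  stopifnot(dt > 0)
  p <- params
  if (is.null(growth_rate))
    growth_rate <- p$r_base *
      .state_penalty(isTRUE(state$sucC_state), isTRUE(state$alsS_state), p)
  state$F_sucC <- .reporter_step(state$F_sucC,
                                 if (isTRUE(state$sucC_state)) p$beta_on else p$beta_off,
                                 growth_rate, dt)
  state$F_alsS <- .reporter_step(state$F_alsS,
                                 if (isTRUE(state$alsS_state)) p$beta_on else p$beta_off,
                                 growth_rate, dt)
  state
}
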