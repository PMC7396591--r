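#' Seeded fermentation simulator (logistic growth, Luedeking-Piret product)
#'
#' Generates fermentation time courses with known ground truth so every
#' downstream yield calculation can be validated end to end. The model is
#' logistic biomass growth with Luedeking-Piret product kinetics and yield-
#' coupled substrate drain:
#' \deqn{dX/dt = \mu_{max} X (1 - X/X_{max})}
#' \deqn{dP/dt = \alpha\, dX/dt + \beta X}
#' \deqn{dS/dt = -(1/Y_{XS})\, dX/dt - (1/Y_{PS})\, dP/dt}
#' Feeds are instantaneous additions of substrate (g/L-equivalent against a
#' constant broth volume); when S reaches 0, growth and production halt
#' until the next feed. Independent Gaussian noise of standard deviation
#' `noise_sd` is added to the observed substrate, product and CDW
#' concentrations (truncated at 0); OD600 is reported as CDW / 0.36. The
#' reported CDW is total dry weight — catalytic biomass X plus intracellular
#' product P — so the polymer content of the culture is `product / cdw`. A
#' fixed seed gives bit-identical output.
#'
#' With `beta = 0` the observed product-per-substrate yield is
#' `alpha / (1/y_xs + alpha/y_ps)` exactly at every sampling time, which is
#' how [phb_flask_params()] pins a known true yield.
#'
#' @param mu_max maximum specific growth rate, 1/h.
#' @param x_max biomass carrying capacity, g CDW/L.
#' @param x0 inoculum, g CDW/L (must be < `x_max`).
#' @param y_xs biomass yield on substrate, g CDW per g.
#' @param alpha growth-associated product coefficient, g product per g CDW.
#' @param beta non-growth-associated rate, g product per g CDW per h.
#' @param y_ps true product-on-substrate yield used for the product drain,
#'   g/g (required > 0 when product is formed).
#' @param s0 initial substrate, g/L.
#' @param feeds data.frame with columns `time` (h) and `amount`
#'   (g/L-equivalent), or `NULL`.
#' @param noise_sd observation noise standard deviation, g/L.
#' @param seed integer random seed (mandatory).
#' @param substrate substrate name used for the output column.
#' @return `fermentation_sim_params()`: a validated parameter object.
#' @examples
#' p <- phb_flask_params(seed = 1)
#' ts <- simulate_fermentation(p, times = seq(0, 54, by = 6))
#' fermentation_summary(ts, "ethanol")
#' @export
fermentation_sim_params <- function(mu_max, x_max, x0, y_xs, alpha, beta,
                                    y_ps, s0, feeds = NULL, noise_sd = 0,
                                    seed, substrate = "ethanol") {
  stopifnot(mu_max >= 0, x_max > 0, x0 > 0, y_xs > 0, alpha >= 0, beta >= 0,
            s0 >= 0, noise_sd >= 0)
  if (x0 >= x_max) stop("x0 must be < x_max", call. = FALSE)
  if ((alpha > 0 || beta > 0) && (missing(y_ps) || y_ps <= 0))
    stop("y_ps must be > 0 when product is formed", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  if (!is.null(feeds)) {
    stopifnot(is.data.frame(feeds), all(c("time", "amount") %in% names(feeds)),
              all(feeds$amount >= 0), all(feeds$time > 0))
    feeds <- feeds[order(feeds$time), , drop = FALSE]
  }
  structure(list(mu_max = mu_max, x_max = x_max, x0 = x0, y_xs = y_xs,
                 alpha = alpha, beta = beta,
                 y_ps = if (missing(y_ps)) 1 else y_ps, s0 = s0,
                 feeds = feeds, noise_sd = noise_sd,
                 seed = as.integer(seed), substrate = substrate),
            class = "fermentation_sim_params")
}

#' @rdname fermentation_sim_params
#' @param yield target observed product-per-substrate yield (g/g) of the
#'   emulated shake-flask culture.
#' @details `phb_flask_params()` emulates a 10 g/L ethanol shake flask:
#'   inoculum 0.05 g/L growing logistically at 0.2/h to 3.3 g/L residual
#'   CDW over ~54 h, purely growth-associated PHB at `alpha = 0.95` g/g
#'   (polymer roughly half of total dry weight), product drain at the
#'   stoichiometric limit `y_ps = 0.935` g/g, and `y_xs` back-calculated so
#'   the realized overall yield equals `yield` (0.32 g/g by default).
#' @export
phb_flask_params <- function(seed, yield = 0.32, noise_sd = 0) {
  alpha <- 0.95
  y_ps <- 0.935
  if (yield >= y_ps) stop("target yield must be below y_ps", call. = FALSE)
  y_xs <- 1 / (alpha / yield - alpha / y_ps)
  fermentation_sim_params(mu_max = 0.2, x_max = 3.3, x0 = 0.05, y_xs = y_xs,
                          alpha = alpha, beta = 0, y_ps = y_ps, s0 = 10,
                          noise_sd = noise_sd, seed = seed,
                          substrate = "ethanol")
}

#' @rdname fermentation_sim_params
#' @param p a `fermentation_sim_params`.
#' @param times sampling times, h (strictly increasing, starting >= 0).
#' @return `simulate_fermentation()`: a [fermentation_timecourse()].
#' @export
simulate_fermentation <- function(p, times) {
  stopifnot(inherits(p, "fermentation_sim_params"))
  times <- sort(unique(times))
  if (any(times < 0)) stop("sampling times must be >= 0", call. = FALSE)
  horizon <- max(times)
  feed_t <- if (is.null(p$feeds)) numeric(0) else p$feeds$time
  if (length(feed_t) > 0 && any(feed_t > horizon))
    stop("feed outside the sampling horizon", call. = FALSE)

  deriv <- function(t, y, parms) {
    if (y[["S"]] <= 0) return(list(c(0, 0, 0)))
    dX <- p$mu_max * y[["X"]] * (1 - y[["X"]] / p$x_max)
    dP <- p$alpha * dX + p$beta * y[["X"]]
    dS <- -dX / p$y_xs - dP / p$y_ps
    list(c(dX, dP, dS))
  }
  rootfn <- function(t, y, parms) y[["S"]]

  res <- matrix(NA_real_, length(times), 3,
                dimnames = list(NULL, c("X", "P", "S")))
  state <- c(X = p$x0, P = 0, S = p$s0)
  if (times[1] == 0) res[1, ] <- state
  breaks <- sort(unique(c(0, feed_t, horizon)))

  for (k in seq_len(max(length(breaks) - 1, 0))) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    if (t0 %in% feed_t)   # instantaneous feed at segment start
      state[["S"]] <- state[["S"]] + sum(p$feeds$amount[p$feeds$time == t0])
    want <- times[times > t0 & times <= t1]
    seg_times <- sort(unique(c(t0, want, t1)))
    if (state[["S"]] > 0 && p$mu_max > 0 && length(seg_times) > 1) {
      sol <- as.matrix(deSolve::lsoda(state, seg_times, deriv, parms = NULL,
                                      rtol = 1e-10, atol = 1e-12,
                                      rootfunc = rootfn))
      held <- sol[nrow(sol), c("X", "P", "S")]
      held[["S"]] <- 0  # state after a substrate-exhaustion stop
      value_at <- function(st) {
        i <- which(abs(sol[, "time"] - st) < 1e-9)
        if (length(i) > 0) sol[i[1], c("X", "P", "S")] else held
      }
    } else {
      value_at <- function(st) state
    }
    for (w in want) res[which(times == w)[1], ] <- pmax(value_at(w), 0)
    state <- pmax(value_at(t1), 0)
    names(state) <- c("X", "P", "S")
  }

  fed_cum <- vapply(times, function(t) {
    if (length(feed_t) == 0) 0 else
      sum(p$feeds$amount[p$feeds$time < t])  # samples at a feed time are pre-feed
  }, 0)

  set.seed(p$seed)
  nz <- function(v) pmax(v + stats::rnorm(length(v), sd = p$noise_sd), 0)
  # reported CDW is total dry weight: catalytic biomass plus intracellular
  # polymer (polymer content = product / CDW, as assayed gravimetrically)
  cdw_true <- res[, "X"] + res[, "P"]
  cdw <- if (p$noise_sd > 0) nz(cdw_true) else cdw_true
  prod <- if (p$noise_sd > 0) nz(res[, "P"]) else res[, "P"]
  subs <- if (p$noise_sd > 0) nz(res[, "S"]) else res[, "S"]

  out <- data.frame(time_h = times, od600 = cdw / 0.36, cdw_g_per_L = cdw,
                    s = subs, product_g_per_L = prod, fed_g_per_L = fed_cum)
  names(out)[names(out) == "s"] <- paste0(p$substrate, "_g_per_L")
  fermentation_timecourse(out)
}

#' Seeded metabolite-panel simulator
#'
#' Generates a replicate metabolite panel with known true cell means:
#' replicate intensities are drawn lognormal with the specified mean and
#' coefficient of variation (`cv = 0` reproduces the cell means exactly),
#' emulating multiplicative LC-MS measurement error; listed undetectable
#' cells are emitted as missing in every replicate. Seeded and
#' deterministic.
#'
#' @param means data.frame with columns `metabolite`, `strain`, `stage`,
#'   `mean` (> 0) giving the true mean of each cell.
#' @param cv coefficient of variation of the lognormal replicate noise.
#' @param n_reps replicates per cell (default 7).
#' @param undetectable optional data.frame with columns `metabolite`,
#'   `strain`, `stage` listing cells to emit as all-undetectable.
#' @param seed integer random seed (mandatory).
#' @return `panel_sim_params()`: a parameter object;
#'   `simulate_panel()`: a [metabolite_panel()].
#' @examples
#' p <- panel_sim_params(
#'   means = data.frame(metabolite = "lactate", strain = c("A", "B"),
#'                      stage = "D1", mean = c(229.22, 1)),
#'   cv = 0, seed = 7)
#' pan <- simulate_panel(p)
#' fold_change(pan, "lactate", c("A", "D1"), c("B", "D1"))$ratio  # 229.22
#' @export
panel_sim_params <- function(means, cv = 0.1, n_reps = 7, undetectable = NULL,
                             seed) {
  stopifnot(is.data.frame(means),
            all(c("metabolite", "strain", "stage", "mean") %in% names(means)),
            all(means$mean > 0), cv >= 0, n_reps >= 1)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  if (!is.null(undetectable))
    stopifnot(is.data.frame(undetectable),
              all(c("metabolite", "strain", "stage") %in% names(undetectable)))
  structure(list(means = means, cv = cv, n_reps = as.integer(n_reps),
                 undetectable = undetectable, seed = as.integer(seed)),
            class = "panel_sim_params")
}

#' @rdname panel_sim_params
#' @param p a `panel_sim_params`.
#' @export
simulate_panel <- function(p) {
  stopifnot(inherits(p, "panel_sim_params"))
  set.seed(p$seed)
  sdlog <- sqrt(log(1 + p$cv^2))
  rows <- lapply(seq_len(nrow(p$means)), function(i) {
    m <- p$means[i, ]
    und <- !is.null(p$undetectable) &&
      any(p$undetectable$metabolite == m$metabolite &
            p$undetectable$strain == m$strain &
            p$undetectable$stage == m$stage)
    intens <- if (und) {
      rep(NA_real_, p$n_reps)
    } else if (p$cv == 0) {
      rep(m$mean, p$n_reps)
    } else {
      stats::rlnorm(p$n_reps, meanlog = log(m$mean) - sdlog^2 / 2,
                    sdlog = sdlog)
    }
    data.frame(metabolite = m$metabolite, strain = m$strain, stage = m$stage,
               replicate = seq_len(p$n_reps), intensity = intens)
  })
  metabolite_panel(do.call(rbind, rows))
}
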