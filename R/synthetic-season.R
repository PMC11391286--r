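#' Ground truth for a simulated roosting season
#'
#' Generative counterpart of the per-night mixed-model analyses: per-night
#' covariates are drawn from uniform ranges, and the behavioural responses
#' are produced by linear predictors on scaled covariates plus site and month
#' random intercepts plus Gaussian residuals. The logit of the overnight
#' calling proportion responds to scaled overnight noise; the pre-departure
#' slope responds to scaled (logit) overnight calling.
#'
#' @param n_sites Number of roost sites.
#' @param nights_per_site Nights per site (>= 2).
#' @param beta_noise_on_nightcall Effect of scaled overnight noise on the
#'   logit overnight-calling proportion. Default 0.4, the magnitude scale of
#'   the field estimate this pipeline is designed to recover.
#' @param beta_nightcall_on_depslope Effect of scaled overnight calling on
#'   the pre-departure slope (negative: disturbed nights blunt the morning
#'   crescendo).
#' @param beta_noise_on_settle Effect of scaled pre-arrival noise on the
#'   settling slope (positive: noisier arrivals settle more slowly).
#' @param beta_nightcall_on_cohesion Effect of scaled overnight calling on
#'   departure cohesion (largest-group proportion, logit scale).
#' @param site_sd,month_sd Random-intercept standard deviations.
#' @param residual_sd Residual standard deviation (per response, on its
#'   modelling scale).
#' @param covariate_ranges Named list of `[min, max]` ranges for
#'   `noise_prearrival`, `noise_overnight`, `noise_predeparture` (nPSD
#'   units), `roost_size` (birds), `temp_mean` (deg C), `wind_mean` (knots),
#'   `light_mean` (lux).
#' @param rain_prob Probability a night has any rain (binary covariate).
#' @param intercepts Named list: `nightcall_logit`, `settle`, `depslope`,
#'   `cohesion_logit`, `empty_s`.
#' @return An object of class `season_truth`.
#' @export
season_truth <- function(n_sites = 5, nights_per_site = 24,
                         beta_noise_on_nightcall = 0.4,
                         beta_nightcall_on_depslope = -0.3,
                         beta_noise_on_settle = 0,
                         beta_nightcall_on_cohesion = 0,
                         site_sd = 0.3, month_sd = 0.2, residual_sd = 0.5,
                         covariate_ranges = list(
                           noise_prearrival = c(0.05, 0.6),
                           noise_overnight = c(0.05, 0.6),
                           noise_predeparture = c(0.05, 0.6),
                           roost_size = c(90, 1500),
                           temp_mean = c(0, 12),
                           wind_mean = c(2, 30),
                           light_mean = c(0, 30)
                         ),
                         rain_prob = 0.4,
                         intercepts = list(nightcall_logit = -1.5,
                                           settle = -0.8, depslope = 0.35,
                                           cohesion_logit = -1,
                                           empty_s = 1800)) {
  if (nights_per_site < 2) stop("nights_per_site must be >= 2")
  if (site_sd < 0 || month_sd < 0 || residual_sd < 0)
    stop("standard deviations must be non-negative")
  structure(as.list(environment()), class = "season_truth")
}

scale0 <- function(x) {
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Simulate a season of per-night metrics with known effects
#'
#' Draws one row per roost-night: covariates from the truth's uniform
#' ranges, responses from the truth's linear predictors with site and month
#' random intercepts. Proportion responses are formed on the logit scale and
#' back-transformed to (0, 1).
#'
#' @param truth A [season_truth()].
#' @param seed Integer seed.
#' @return A data frame with one row per night (site, date, month,
#'   covariates, and the response columns `settle_slope`,
#'   `night_call_prop`, `predeparture_slope`, `largest_group_prop`,
#'   `time_to_empty_s`), with the realized random intercepts attached as
#'   attribute `"ranef_truth"`.
#' @examples
#' season <- simulate_season(season_truth(n_sites = 3, nights_per_site = 4),
#'                           seed = 1)
#' head(season)
#' @export
simulate_season <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "season_truth"))
  tr <- truth
  with_seed(seed, {
    n <- tr$n_sites * tr$nights_per_site
    site <- rep(paste0("S", seq_len(tr$n_sites)), each = tr$nights_per_site)
    months <- c("Nov", "Dec", "Jan", "Feb", "Mar")
    month <- rep_len(rep(months, length.out = tr$nights_per_site), n)
    month_start <- c(Nov = "2021-11-01", Dec = "2021-12-01",
                     Jan = "2022-01-01", Feb = "2022-02-01",
                     Mar = "2022-03-01")
    date <- as.Date(month_start[month]) +
      as.integer(stats::ave(seq_len(n), site, month, FUN = seq_along)) - 1L
    draw <- function(nm) {
      r <- tr$covariate_ranges[[nm]]
      stats::runif(n, r[1], r[2])
    }
    dat <- data.frame(
      site = site, date = date, month = month,
      noise_prearrival = draw("noise_prearrival"),
      noise_overnight = draw("noise_overnight"),
      noise_predeparture = draw("noise_predeparture"),
      roost_size = round(draw("roost_size")),
      temp_mean = draw("temp_mean"),
      wind_mean = draw("wind_mean"),
      rain = stats::rbinom(n, 1, tr$rain_prob),
      light_mean = draw("light_mean"),
      stringsAsFactors = FALSE
    )
    re <- function(labels, sd) {
      u <- stats::rnorm(length(unique(labels)), 0, sd)
      names(u) <- unique(labels)
      u[labels]
    }
    eps <- function() stats::rnorm(n, 0, tr$residual_sd)

    site_re_nc <- re(site, tr$site_sd)
    month_re_nc <- re(month, tr$month_sd)
    nightcall_logit <- tr$intercepts$nightcall_logit +
      tr$beta_noise_on_nightcall * scale0(dat$noise_overnight) +
      site_re_nc + month_re_nc + eps()
    dat$night_call_prop <- stats::plogis(nightcall_logit)

    nc_z <- scale0(nightcall_logit)
    dat$predeparture_slope <- tr$intercepts$depslope +
      tr$beta_nightcall_on_depslope * nc_z +
      re(site, tr$site_sd) + re(month, tr$month_sd) + eps()

    dat$settle_slope <- tr$intercepts$settle +
      tr$beta_noise_on_settle * scale0(dat$noise_prearrival) +
      re(site, tr$site_sd) + re(month, tr$month_sd) + eps()

    dat$largest_group_prop <- stats::plogis(
      tr$intercepts$cohesion_logit +
        tr$beta_nightcall_on_cohesion * nc_z +
        re(site, tr$site_sd) + re(month, tr$month_sd) + eps()
    )
    dat$time_to_empty_s <- pmax(
      0, tr$intercepts$empty_s + 300 * (re(site, tr$site_sd) +
                                          re(month, tr$month_sd) + eps())
    )
    attr(dat, "ranef_truth") <- list(site_nightcall = site_re_nc,
                                     month_nightcall = month_re_nc)
    dat
  })
}
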