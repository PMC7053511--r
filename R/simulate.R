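#' Per-activity social profile for the synthetic generator
#'
#' A social profile controls how the animals performing one activity in one
#' period organize into proximity groups:
#' \itemize{
#'   \item `mean_group_size`: expected size of a proximity group (>= 1);
#'     group sizes are drawn as 1 + Poisson(mean_group_size - 1).
#'   \item `group_closure`: probability that a within-group pair beyond the
#'     group's spanning chain is connected; 0 gives chains, 1 gives cliques.
#'     This is the knob that drives the clustering coefficient.
#'   \item `participation_bias_age`: slope on standardized age in the
#'     per-animal activity weights; negative values make older animals less
#'     likely to take part in (and hence form proximity during) this activity.
#'   \item `participation_bias_male`: additive log-weight for males.
#'   \item `hub_attachment`: probability that an active animal attaches
#'     directly to a designated hub animal instead of joining a group; drives
#'     star-like structure and hence eigenvector centrality in sparse
#'     activities.
#' }
#'
#' @param activity one of [activities()].
#' @param mean_group_size positive real.
#' @param group_closure probability in \[0, 1\].
#' @param participation_bias_age real slope on standardized age.
#' @param participation_bias_male real additive effect for males.
#' @param hub_attachment probability in \[0, 1\].
#' @return A `social_profile` list.
#' @export
social_profile <- function(activity, mean_group_size = 3,
                           group_closure = 0.2,
                           participation_bias_age = 0,
                           participation_bias_male = 0,
                           hub_attachment = 0) {
  check_activity(activity)
  stopifnot(length(activity) == 1L,
            mean_group_size >= 1,
            group_closure >= 0, group_closure <= 1,
            hub_attachment >= 0, hub_attachment <= 1)
  structure(list(activity = activity,
                 mean_group_size = mean_group_size,
                 group_closure = group_closure,
                 participation_bias_age = participation_bias_age,
                 participation_bias_male = participation_bias_male,
                 hub_attachment = hub_attachment),
            class = "social_profile")
}

#' Default social profiles
#'
#' One profile per activity, emulating the qualitative herd structure the
#' pipeline is designed to detect: grazing cohesive and clustered (large,
#' nearly closed groups), moving and standing intermediate with a negative
#' age bias and a positive male bias, the resting activities (ruminating,
#' wallowing, drinking) sparse with small open groups, and lying sparse but
#' hub-attached (star-shaped proximity around designated animals).
#'
#' @return Named list of [social_profile()] objects, one per activity.
#' @export
default_profiles <- function() {
  list(
    grazing    = social_profile("grazing", mean_group_size = 9,
                                group_closure = 0.85),
    moving     = social_profile("moving", mean_group_size = 5,
                                group_closure = 0.30,
                                participation_bias_age = -0.8,
                                participation_bias_male = 1.2),
    standing   = social_profile("standing", mean_group_size = 5,
                                group_closure = 0.25,
                                participation_bias_age = -0.8,
                                participation_bias_male = 1.2),
    ruminating = social_profile("ruminating", mean_group_size = 2.5,
                                group_closure = 0.15,
                                participation_bias_age = -0.3),
    wallowing  = social_profile("wallowing", mean_group_size = 2.5,
                                group_closure = 0.10,
                                participation_bias_age = -0.8),
    lying      = social_profile("lying", mean_group_size = 5,
                                group_closure = 0.10,
                                participation_bias_age = -0.3,
                                hub_attachment = 1.0),
    drinking   = social_profile("drinking", mean_group_size = 2,
                                group_closure = 0.0,
                                participation_bias_age = -0.3)
  )
}

#' Default activity prevalence
#'
#' Baseline multinomial probabilities of the seven activities in a period.
#' The herd's field time budgets are not published; these are plausibility
#' choices that keep grazing dominant and the resting activities rare.
#'
#' @return Named numeric vector over [activities()], summing to 1.
#' @export
default_prevalence <- function() {
  c(grazing = 0.44, moving = 0.15, standing = 0.12, ruminating = 0.14,
    wallowing = 0.05, lying = 0.08, drinking = 0.02)
}

#' Generator configuration
#'
#' Bundles everything the synthetic-herd generator needs. Defaults mirror the
#' reference observation design: 88 females aged 0.5-23 years with mean about
#' 9 years, 3 males aged 2.5-3 years, and 240 observation periods
#' (12 months x 2 days x 5 hours x 2 half-hour steps).
#'
#' @param seed integer master seed; all generator randomness derives from it.
#' @param n_female,n_male non-negative counts (total >= 1).
#' @param female_age_range,male_age_range length-2 ranges in years.
#' @param female_age_mean,female_age_sd parameters of the truncated normal the
#'   female ages are drawn from.
#' @param n_periods number of observation periods.
#' @param activity_prevalence named probability vector over [activities()];
#'   must sum to 1 (tolerance 1e-9).
#' @param profiles named list of [social_profile()]s, one per activity.
#' @param n_hubs number of designated hub animals per hub-attached activity.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_female = 88L, n_male = 3L,
                             female_age_range = c(0.5, 23),
                             female_age_mean = 9,
                             female_age_sd = 5.5,
                             male_age_range = c(2.5, 3),
                             n_periods = 240L,
                             activity_prevalence = default_prevalence(),
                             profiles = default_profiles(),
                             n_hubs = 1L) {
  config <- list(seed = as.integer(seed),
                 n_female = as.integer(n_female),
                 n_male = as.integer(n_male),
                 female_age_range = as.numeric(female_age_range),
                 female_age_mean = as.numeric(female_age_mean),
                 female_age_sd = as.numeric(female_age_sd),
                 male_age_range = as.numeric(male_age_range),
                 n_periods = as.integer(n_periods),
                 activity_prevalence = activity_prevalence,
                 profiles = profiles,
                 n_hubs = as.integer(n_hubs))
  validate_generator_config(config)
}

validate_generator_config <- function(config) {
  stopifnot(is.list(config))
  if (config$n_female < 0L || config$n_male < 0L ||
      config$n_female + config$n_male < 1L) {
    stop("herd must contain at least one animal", call. = FALSE)
  }
  if (config$n_periods < 1L) stop("n_periods must be positive", call. = FALSE)
  prev <- config$activity_prevalence
  missing <- setdiff(activities(), names(prev))
  if (length(missing) > 0L) {
    stop(sprintf("activity_prevalence is missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  prev <- prev[activities()]
  if (any(prev < 0) || abs(sum(prev) - 1) > 1e-9) {
    stop("activity_prevalence must be non-negative and sum to 1", call. = FALSE)
  }
  config$activity_prevalence <- prev
  missing <- setdiff(activities(), names(config$profiles))
  if (length(missing) > 0L) {
    stop(sprintf("profiles are missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  config$profiles <- config$profiles[activities()]
  class(config) <- c("generator_config", "list")
  config
}

#' Read a generator configuration from YAML/JSON
#'
#' The file mirrors [generator_config()]: scalar fields at the top level, a
#' named `activity_prevalence` map, and a named `profiles` map whose entries
#' hold the [social_profile()] fields. Omitted fields keep their defaults.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (fld in c("seed", "n_female", "n_male", "female_age_range",
                "female_age_mean", "female_age_sd", "male_age_range",
                "n_periods", "n_hubs")) {
    if (!is.null(raw[[fld]])) args[[fld]] <- raw[[fld]]
  }
  if (!is.null(raw$activity_prevalence)) {
    args$activity_prevalence <- unlist(raw$activity_prevalence)
  }
  if (!is.null(raw$profiles)) {
    profs <- default_profiles()
    for (a in names(raw$profiles)) {
      profs[[a]] <- do.call(social_profile, c(list(activity = a),
                                              raw$profiles[[a]]))
    }
    args$profiles <- profs
  }
  do.call(generator_config, args)
}

# truncated-normal draws by rejection (ranges here are wide, acceptance high)
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# location mu such that the [lower, upper]-truncated N(mu, sd) has the target
# mean (asymmetric truncation shifts the mean, so mu != target in general)
trunc_norm_location <- function(target, sd, lower, upper) {
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 interval = c(lower - 2 * sd, upper + 2 * sd),
                 tol = 1e-8)$root
}

#' Generate a synthetic roster
#'
#' Female ages are truncated-normal within `female_age_range` (mean near
#' `female_age_mean`); male ages are uniform within `male_age_range`. IDs are
#' `B01`, `B02`, ... with females first. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return A `herd_roster`.
#' @export
generate_roster <- function(config) {
  config <- validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_female + config$n_male
  ids <- sprintf("B%0*d", max(2L, nchar(n)), seq_len(n))
  age_f <- if (config$n_female > 0L) {
    mu <- trunc_norm_location(config$female_age_mean, config$female_age_sd,
                              config$female_age_range[1],
                              config$female_age_range[2])
    round(rtruncnorm_reject(config$n_female, mu, config$female_age_sd,
                            config$female_age_range[1],
                            config$female_age_range[2]), 1)
  } else numeric(0)
  age_m <- if (config$n_male > 0L) {
    round(stats::runif(config$n_male, config$male_age_range[1],
                       config$male_age_range[2]), 1)
  } else numeric(0)
  herd_roster(ids, c(age_f, age_m),
              c(rep(1L, config$n_female), rep(2L, config$n_male)))
}

# edges for one (activity, period): hub stars then chain+closure groups;
# S and hubs are integer vertex indices; returns a 2-column index matrix
activity_edges <- function(S, prof, hubs) {
  edges <- matrix(integer(0), ncol = 2)
  if (length(S) < 2L) return(edges)
  pool <- S
  if (prof$hub_attachment > 0) {
    hp <- intersect(hubs, S)
    if (length(hp) == 0L) hp <- S[sample.int(length(S), 1L)]
    others <- setdiff(S, hp)
    if (length(others) > 0L) {
      attach <- others[stats::runif(length(others)) < prof$hub_attachment]
      if (length(attach) > 0L) {
        centers <- hp[sample.int(length(hp), length(attach), replace = TRUE)]
        edges <- rbind(edges, cbind(attach, centers))
      }
      pool <- setdiff(others, attach)
    } else {
      pool <- integer(0)
    }
  }
  if (length(pool) >= 2L) {
    perm <- pool[sample.int(length(pool))]
    sizes <- integer(0)
    left <- length(perm)
    while (left > 0L) {
      k <- min(left, 1L + stats::rpois(1L, max(prof$mean_group_size - 1, 0)))
      sizes <- c(sizes, k)
      left <- left - k
    }
    at <- 0L
    for (k in sizes) {
      grp <- perm[(at + 1L):(at + k)]
      at <- at + k
      if (k >= 2L) {
        edges <- rbind(edges, cbind(grp[-k], grp[-1L]))  # spanning chain
        if (k >= 3L && prof$group_closure > 0) {
          pairs <- utils::combn(sort(grp), 2L)
          chain <- paste(pmin(grp[-k], grp[-1L]), pmax(grp[-k], grp[-1L]))
          extra <- pairs[, !(paste(pairs[1L, ], pairs[2L, ]) %in% chain),
                         drop = FALSE]
          keep <- stats::runif(ncol(extra)) < prof$group_closure
          if (any(keep)) edges <- rbind(edges, t(extra[, keep, drop = FALSE]))
        }
      }
    }
  }
  edges
}

period_calendar <- function(p) {
  # 12 months x 2 daily sessions x 10 half-hour steps
  q <- p - 1L
  list(month = q %/% 20L + 1L,
       session = (q %% 20L) %/% 10L + 1L,
       time_step = q %% 10L + 1L)
}

#' Generate synthetic observation records
#'
#' For each period every animal is assigned exactly one activity from a
#' per-animal multinomial: baseline `activity_prevalence` reweighted by
#' `exp(bias_age * z_age + bias_male * male)` from the activity's
#' [social_profile()] and renormalized. Animals sharing an activity are wired
#' into proximity groups (spanning chain plus closure pairs) or, for
#' hub-attached activities, into stars around designated hub animals.
#' Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @param roster a `herd_roster`, typically from [generate_roster()].
#' @return A validated `herd_records` data frame (one row per animal-period).
#' @export
generate_records <- function(config, roster) {
  config <- validate_generator_config(config)
  roster <- validate_roster(roster)
  set.seed(config$seed + 1L)
  n <- nrow(roster)
  acts <- activities()
  z_age <- if (n > 1L && stats::sd(roster$age) > 0) {
    (roster$age - mean(roster$age)) / stats::sd(roster$age)
  } else rep(0, n)
  male <- as.numeric(roster$gender == 2L)

  w <- matrix(0, n, 7L, dimnames = list(NULL, acts))
  for (k in seq_along(acts)) {
    prof <- config$profiles[[acts[k]]]
    w[, k] <- config$activity_prevalence[acts[k]] *
      exp(prof$participation_bias_age * z_age +
            prof$participation_bias_male * male)
  }
  w <- w / rowSums(w)
  cw <- t(apply(w, 1L, cumsum))

  hubs <- vector("list", 7L)
  names(hubs) <- acts
  for (a in acts) {
    if (config$profiles[[a]]$hub_attachment > 0) {
      hubs[[a]] <- sample.int(n, min(config$n_hubs, n))
    }
  }

  n_per <- config$n_periods
  period_id <- rep(seq_len(n_per), each = n)
  animal_id <- rep(roster$animal_id, times = n_per)
  activity <- character(n * n_per)
  partners <- character(n * n_per)

  for (p in seq_len(n_per)) {
    u <- stats::runif(n)
    act_idx <- rowSums(u > cw) + 1L
    off <- (p - 1L) * n
    activity[off + seq_len(n)] <- acts[act_idx]
    adj <- vector("list", n)
    for (k in seq_len(7L)) {
      S <- which(act_idx == k)
      if (length(S) < 2L) next
      E <- activity_edges(S, config$profiles[[acts[k]]], hubs[[acts[k]]])
      if (nrow(E) > 0L) {
        ends <- c(E[, 1L], E[, 2L])
        nbr <- c(E[, 2L], E[, 1L])
        sp <- split(nbr, ends)
        for (v in names(sp)) {
          vi <- as.integer(v)
          adj[[vi]] <- c(adj[[vi]], sp[[v]])
        }
      }
    }
    has <- which(lengths(adj) > 0L)
    partners[off + has] <- vapply(adj[has], function(ix) {
      paste(sort(unique(roster$animal_id[ix])), collapse = ";")
    }, character(1))
  }

  cal <- lapply(seq_len(n_per), period_calendar)
  months <- vapply(cal, `[[`, integer(1), "month")
  sessions <- vapply(cal, `[[`, integer(1), "session")
  steps <- vapply(cal, `[[`, integer(1), "time_step")

  validate_records(data.frame(
    period_id = period_id,
    month = rep(months, each = n),
    session = rep(sessions, each = n),
    time_step = rep(steps, each = n),
    animal_id = animal_id,
    activity = activity,
    partners = partners,
    stringsAsFactors = FALSE), roster)
}

#' Generate a full synthetic herd study
#'
#' Convenience wrapper: roster plus records from one configuration.
#'
#' @param config a [generator_config()].
#' @return List with elements `roster` and `records`.
#' @export
simulate_herd <- function(config = generator_config()) {
  roster <- generate_roster(config)
  list(roster = roster, records = generate_records(config, roster))
}
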