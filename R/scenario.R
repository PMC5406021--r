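# Declarative demographic scenarios: populations, timed events (splits,
# admixture, Ne changes), serial sample schedules and parameter priors.
# Time is measured internally in generations before present (present =
# 2015 by default, 10 generations per year); calendar years appear only at
# the configuration surface.

#' Prior specification for a scenario parameter
#'
#' @param distribution `"uniform"`, `"loguniform"` or `"normal"`
#'   (truncated normal: `mean`, `sd` plus `min`/`max` bounds).
#' @param min,max finite bounds with `min < max`.
#' @param mean,sd required for `"normal"`.
#' @return A `prior_spec`.
#' @examples
#' prior_spec("loguniform", 1e-6, 1e-3)
#' @export
prior_spec <- function(distribution = c("uniform", "loguniform", "normal"),
                       min, max, mean = NULL, sd = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(is.finite(min), is.finite(max), min < max)
  if (distribution == "loguniform") stopifnot(min > 0)
  if (distribution == "normal") stopifnot(!is.null(mean), !is.null(sd), sd > 0)
  structure(list(distribution = distribution, min = min, max = max,
                 mean = mean, sd = sd), class = "prior_spec")
}

.draw_prior <- function(ps, n) {
  switch(ps$distribution,
    uniform = runif(n, ps$min, ps$max),
    loguniform = exp(runif(n, log(ps$min), log(ps$max))),
    normal = {
      # truncated normal via rejection (bounds are wide in practice)
      out <- numeric(0)
      while (length(out) < n) {
        x <- rnorm(2 * (n - length(out)) + 8, ps$mean, ps$sd)
        out <- c(out, x[x >= ps$min & x <= ps$max])
      }
      out[seq_len(n)]
    })
}

#' Convert calendar years to generations before present
#'
#' `(present - year) * g_per_year`; the study assumption is 10
#' generations per year with present = 2015.
#'
#' @param year calendar year(s), not after `present`.
#' @param present reference year.
#' @param g_per_year generations per calendar year.
#' @return Generations before present.
#' @examples
#' years_to_generations(2005)  # 100
#' @export
years_to_generations <- function(year, present = 2015, g_per_year = 10) {
  if (any(year > present)) stop("year after the reference 'present'")
  (present - year) * g_per_year
}

#' Convert generations before present back to calendar years
#' @param gen generations before present.
#' @inheritParams years_to_generations
#' @export
generations_to_years <- function(gen, present = 2015, g_per_year = 10) {
  present - gen / g_per_year
}

#' Construct a demographic scenario
#'
#' A scenario declares populations, an event list (viewed backward in
#' time), initial effective sizes, parameter priors with optional order
#' conditions, and the serial sample schedule. Numeric fields of events
#' and `ne0` may be numbers or expression strings over parameter names
#' (e.g. `"max(T_TS - DB_TS, 0)"`), evaluated when the scenario is
#' compiled with a parameter draw.
#'
#' Event kinds:
#' * `split`: `pop` (daughter) merges into `parent` at `time` -- the
#'   forward-time origin of `pop`.
#' * `ne_change`: `pop` takes effective size `ne` from `time` backward.
#' * `admixture`: lineages of `pop` move to `parent` with probability
#'   `prob`, otherwise to `parent2`, at `time`.
#'
#' @param id scenario identifier.
#' @param populations character vector of population names (first may be
#'   an unsampled ancestor).
#' @param ne0 named list/vector: initial (present-day) Ne expression per
#'   population.
#' @param events list of event lists with fields `kind`, `time`, `pop`,
#'   and `parent`/`parent2`/`prob`/`ne` as required.
#' @param priors named list of [prior_spec()] objects.
#' @param conditions character vector of logical expressions over
#'   parameters (e.g. `"T_ANC > T_PNG"`), enforced by rejection at
#'   sampling time.
#' @param samples data frame with columns `pop`, `year`, `n` (diploid
#'   individuals per sample event).
#' @param g_per_year,present time conversion settings.
#' @return A `scenario` object.
#' @export
scenario <- function(id, populations, ne0, events, priors,
                     conditions = character(), samples,
                     g_per_year = 10, present = 2015) {
  stopifnot(is.character(populations), !anyDuplicated(populations))
  samples$pop <- as.character(samples$pop)
  structure(list(id = id, populations = populations, ne0 = ne0,
                 events = events, priors = priors, conditions = conditions,
                 samples = samples, g_per_year = g_per_year,
                 present = present),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d populations, %d events, %d parameters\n",
              x$id, length(x$populations), length(x$events),
              length(x$priors)))
  invisible(x)
}

# safe evaluation environment for scenario expressions
.expr_env <- function(params) {
  e <- new.env(parent = baseenv())
  for (nm in names(params)) assign(nm, params[[nm]], envir = e)
  e
}

.eval_field <- function(field, env) {
  if (is.numeric(field)) return(field)
  eval(parse(text = field)[[1]], envir = env)
}

#' Validate a scenario
#'
#' Structural checks: referenced populations exist, every parameter used
#' has a prior, each non-root population merges away exactly once, all
#' sampled populations can reach a single common root, sample years do
#' not postdate the present, and order conditions are acyclic for simple
#' `a > b` forms. Returns violations rather than raising.
#'
#' @param s a `scenario`.
#' @return List with `ok` flag, `violations` character vector, and a
#'   plain-text `timeline` sketch.
#' @export
validate_scenario <- function(s) {
  v <- character(0)
  pops <- s$populations
  merged <- character(0)
  parent_of <- character(0)
  for (ev in s$events) {
    if (!ev$pop %in% pops) v <- c(v, paste("unknown population", ev$pop))
    if (ev$kind %in% c("split", "admixture")) {
      if (!ev$parent %in% pops) v <- c(v, paste("unknown parent", ev$parent))
      if (ev$pop %in% merged)
        v <- c(v, paste(ev$pop, "merges away more than once"))
      merged <- c(merged, ev$pop)
      parent_of[ev$pop] <- ev$parent
    }
    if (ev$kind == "admixture") {
      if (!ev$parent2 %in% pops) v <- c(v, paste("unknown parent", ev$parent2))
    }
  }
  roots <- setdiff(pops, merged)
  if (length(roots) != 1)
    v <- c(v, paste("expected one root population, found:",
                    paste(roots, collapse = ", ")))
  # reachability of sampled pops to the root
  if (length(roots) == 1) {
    for (p in unique(s$samples$pop)) {
      cur <- p; seen <- character(0); ok <- FALSE
      while (!is.na(cur)) {
        if (cur == roots) { ok <- TRUE; break }
        if (cur %in% seen) break
        seen <- c(seen, cur)
        cur <- if (cur %in% names(parent_of)) parent_of[[cur]] else NA
      }
      if (!ok) v <- c(v, paste("sampled population", p,
                               "cannot reach the root"))
    }
  }
  if (any(s$samples$year > s$present))
    v <- c(v, "sample event scheduled after the present")
  # parameter coverage
  used <- unique(unlist(lapply(s$events, function(ev) {
    f <- c(ev$time, ev$ne, ev$prob)
    f <- f[vapply(f, is.character, TRUE)]
    unlist(lapply(f, function(x) all.vars(parse(text = x)[[1]])))
  })))
  used <- union(used, unlist(lapply(s$ne0, function(x)
    if (is.character(x)) all.vars(parse(text = x)[[1]]) else character(0))))
  missing <- setdiff(used, names(s$priors))
  if (length(missing))
    v <- c(v, paste("parameters without priors:",
                    paste(missing, collapse = ", ")))
  # cycle check on simple "a > b" conditions
  simp <- regmatches(s$conditions,
                     regexec("^\\s*(\\w+)\\s*>\\s*(\\w+)\\s*$", s$conditions))
  edges <- do.call(rbind, lapply(simp, function(m)
    if (length(m) == 3) m[2:3] else NULL))
  if (!is.null(edges)) {
    nodes <- unique(c(edges))
    adj <- split(edges[, 2], edges[, 1])
    state <- setNames(rep(0L, length(nodes)), nodes)
    cyc <- FALSE
    visit <- function(u) {
      if (state[[u]] == 1L) { cyc <<- TRUE; return() }
      if (state[[u]] == 2L) return()
      state[[u]] <<- 1L
      for (w in adj[[u]]) visit(w)
      state[[u]] <<- 2L
    }
    for (u in nodes) if (state[[u]] == 0L) visit(u)
    if (cyc) v <- c(v, "order conditions contain a cycle")
  }
  timeline <- paste(
    c(sprintf("scenario %s (present = %d, %d gen/year)", s$id, s$present,
              s$g_per_year),
      vapply(s$events, function(ev)
        sprintf("  [%s] %s %s%s", as.character(ev$time), ev$kind, ev$pop,
                if (!is.null(ev$parent)) paste0(" -> ", ev$parent) else ""),
        "")),
    collapse = "\n")
  list(ok = length(v) == 0, violations = v, timeline = timeline)
}

#' Draw parameter vectors from a scenario's priors
#'
#' Each parameter is drawn from its declared prior; draws violating any
#' order condition are rejected and redrawn as whole vectors.
#'
#' @param s a `scenario`.
#' @param n number of vectors.
#' @param seed RNG seed.
#' @param max_tries rejection budget (multiples of `n`).
#' @return Matrix `n x n_params` with parameter names as columns.
#' @export
sample_priors <- function(s, n = 1, seed = NULL, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  pn <- names(s$priors)
  conds <- lapply(s$conditions, function(cc) parse(text = cc)[[1]])
  out <- matrix(NA_real_, 0, length(pn), dimnames = list(NULL, pn))
  tries <- 0
  while (nrow(out) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not satisfy order conditions after ", max_tries,
           " rounds of rejection")
    m <- max(n - nrow(out), 16)
    draw <- vapply(s$priors, .draw_prior, numeric(m), n = m)
    if (!is.matrix(draw)) draw <- matrix(draw, nrow = m)
    colnames(draw) <- pn
    if (length(conds)) {
      keep <- rep(TRUE, m)
      for (i in seq_len(m)) {
        env <- .expr_env(as.list(draw[i, ]))
        for (cc in conds)
          if (!isTRUE(eval(cc, env))) { keep[i] <- FALSE; break }
      }
      draw <- draw[keep, , drop = FALSE]
    }
    out <- rbind(out, draw)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Compile a scenario with a parameter draw into numeric event tables
#'
#' Evaluates all expression fields against the parameter vector and
#' returns the numeric structures the coalescent engine consumes:
#' 0-based population indices, an event table sorted by time, initial Ne
#' per population, and the sample schedule in generations.
#'
#' @param s a `scenario`.
#' @param params named numeric vector (one row of [sample_priors()]).
#' @return A `compiled_scenario` list.
#' @export
compile_scenario <- function(s, params) {
  env <- .expr_env(as.list(params))
  pops <- s$populations
  pidx <- function(p) match(p, pops) - 1L
  ne0 <- vapply(pops, function(p) {
    f <- s$ne0[[p]]
    if (is.null(f)) stop("no initial Ne for population ", p)
    as.numeric(.eval_field(f, env))
  }, 0)
  ev <- lapply(s$events, function(e) {
    t <- as.numeric(.eval_field(e$time, env))
    switch(e$kind,
      split = list(time = t, type = 1L, pop = pidx(e$pop),
                   dest = pidx(e$parent), dest2 = -1L, prob = 1, ne = 0),
      ne_change = list(time = t, type = 0L, pop = pidx(e$pop), dest = -1L,
                       dest2 = -1L, prob = 0,
                       ne = as.numeric(.eval_field(e$ne, env))),
      admixture = list(time = t, type = 2L, pop = pidx(e$pop),
                       dest = pidx(e$parent), dest2 = pidx(e$parent2),
                       prob = as.numeric(.eval_field(e$prob, env)), ne = 0),
      stop("unknown event kind ", e$kind))
  })
  ord <- order(vapply(ev, `[[`, 0, "time"))
  ev <- ev[ord]
  samples <- data.frame(
    pop = pidx(s$samples$pop),
    time = years_to_generations(s$samples$year, s$present, s$g_per_year),
    n = s$samples$n)
  structure(list(
    npop = length(pops), populations = pops, ne0 = unname(ne0),
    ev_time = vapply(ev, `[[`, 0, "time"),
    ev_type = vapply(ev, `[[`, 0L, "type"),
    ev_pop = vapply(ev, `[[`, 0L, "pop"),
    ev_dest = vapply(ev, `[[`, 0L, "dest"),
    ev_dest2 = vapply(ev, `[[`, 0L, "dest2"),
    ev_prob = vapply(ev, `[[`, 0, "prob"),
    ev_ne = vapply(ev, `[[`, 0, "ne"),
    samples = samples, params = params), class = "compiled_scenario")
}

#' Serialize a scenario to YAML / read it back
#'
#' The YAML form carries everything [scenario()] takes, so write-read
#' round-trips are lossless.
#'
#' @param s a `scenario`.
#' @param path file path.
#' @export
write_scenario_yaml <- function(s, path) {
  pr <- lapply(s$priors, function(p)
    Filter(Negate(is.null), list(distribution = p$distribution, min = p$min,
                                 max = p$max, mean = p$mean, sd = p$sd)))
  obj <- list(id = s$id, populations = as.list(s$populations),
              ne0 = s$ne0, events = s$events, priors = pr,
              conditions = as.list(s$conditions),
              samples = list(pop = as.list(s$samples$pop),
                             year = as.list(s$samples$year),
                             n = as.list(s$samples$n)),
              g_per_year = s$g_per_year, present = s$present)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  priors <- lapply(o$priors, function(p)
    prior_spec(p$distribution, p$min, p$max, p$mean, p$sd))
  scenario(id = o$id, populations = unlist(o$populations), ne0 = o$ne0,
           events = o$events, priors = priors,
           conditions = unlist(o$conditions) %||% character(),
           samples = data.frame(pop = unlist(o$samples$pop),
                                year = unlist(o$samples$year),
                                n = unlist(o$samples$n)),
           g_per_year = o$g_per_year, present = o$present)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the five Australasian invasion scenarios
#'
#' Seven populations are modelled: an unsampled ancestor (ANC) splitting
#' into mainland SE Asia (SEA) and Indonesia (IDN), plus Papua (PAP),
#' Papua New Guinea (PNG), the Solomon Islands (SOL) and the Torres
#' Strait/Southern Fly region (TS). All scenarios introduce TS from IDN
#' and differ in the sources of the New Guinea and Solomon Islands
#' introductions; scenario 1 equals scenario 4 except that SOL originates
#' from SEA rather than PNG. Every introduction carries a founder
#' bottleneck: a reduced-Ne epoch of prior duration immediately after the
#' introduction. PNG and TS carry additional temporal samples. Default
#' priors centre the introduction times on the historical first-detection
#' years (Papua 1962, PNG 1972, Solomons 1979, TS 2005) and give the
#' ANC split a log-uniform prior over 1,790-27,600 years before present;
#' all are overridable through `prior_overrides`.
#'
#' @param prior_overrides named list of [prior_spec()] objects replacing
#'   the defaults.
#' @param include_admixture also return an optional sixth scenario in
#'   which SOL is an SEA x PNG admixture.
#' @return Named list of `scenario` objects (`s1`..`s5`, optionally
#'   `s6_admix`).
#' @export
build_study_scenarios <- function(prior_overrides = list(),
                                  include_admixture = FALSE) {
  g <- 10; present <- 2015
  y2g <- function(y) (present - y) * g
  priors <- list(
    N_ANC = prior_spec("uniform", 10, 1e6),
    N_SEA = prior_spec("uniform", 10, 1e6),
    N_IDN = prior_spec("uniform", 10, 1e6),
    N_PAP = prior_spec("uniform", 10, 1e6),
    N_PNG = prior_spec("uniform", 10, 1e6),
    N_SOL = prior_spec("uniform", 10, 1e6),
    N_TS  = prior_spec("uniform", 10, 1e6),
    NF_PAP = prior_spec("uniform", 10, 1e4),
    NF_PNG = prior_spec("uniform", 10, 1e4),
    NF_SOL = prior_spec("uniform", 10, 1e4),
    NF_TS  = prior_spec("uniform", 10, 1e4),
    DB_PAP = prior_spec("uniform", 1, 100),
    DB_PNG = prior_spec("uniform", 1, 100),
    DB_SOL = prior_spec("uniform", 1, 100),
    DB_TS  = prior_spec("uniform", 1, 60),
    T_PAP = prior_spec("normal", 20, 950, mean = y2g(1962), sd = 150),
    T_PNG = prior_spec("normal", 210, 900, mean = y2g(1972), sd = 100),
    T_SOL = prior_spec("normal", 20, 700, mean = y2g(1979), sd = 60),
    T_TS  = prior_spec("normal", 82, 300, mean = y2g(2005), sd = 20),
    T_ANC = prior_spec("loguniform", 17900, 276000),
    MU_DI  = prior_spec("loguniform", 1e-6, 1e-3),
    MU_TRI = prior_spec("loguniform", 1e-6, 1e-3),
    P_GSM_DI  = prior_spec("uniform", 0.1, 1),
    P_GSM_TRI = prior_spec("uniform", 0.1, 1),
    MU_SEQ = prior_spec("uniform", 7e-10, 1e-7),
    KAPPA = prior_spec("uniform", 2, 20)
  )
  for (nm in names(prior_overrides)) priors[[nm]] <- prior_overrides[[nm]]

  pops <- c("ANC", "SEA", "IDN", "PAP", "PNG", "SOL", "TS")
  ne0 <- list(ANC = "N_ANC", SEA = "N_SEA", IDN = "N_IDN", PAP = "N_PAP",
              PNG = "N_PNG", SOL = "N_SOL", TS = "N_TS")
  samples <- data.frame(
    pop = c("SEA", "IDN", "PAP", "PNG", "PNG", "SOL", "TS", "TS"),
    year = c(2015, 2015, 2015, 2015, 1995, 2015, 2015, 2007),
    n = c(30, 30, 20, 30, 30, 30, 30, 30))

  founder <- function(pop) {
    list(list(kind = "ne_change", pop = pop,
              time = sprintf("max(T_%s - DB_%s, 0)", pop, pop),
              ne = sprintf("NF_%s", pop)))
  }
  base_events <- c(
    list(list(kind = "split", pop = "SEA", parent = "ANC", time = "T_ANC"),
         list(kind = "split", pop = "IDN", parent = "ANC", time = "T_ANC"),
         list(kind = "split", pop = "TS", parent = "IDN", time = "T_TS")),
    founder("PAP"), founder("PNG"), founder("SOL"), founder("TS"))
  base_conditions <- c("T_ANC > T_PAP", "T_ANC > T_PNG", "T_ANC > T_SOL",
                       "T_ANC > T_TS", "T_PAP > T_PNG",
                       "DB_PAP < T_PAP", "DB_PNG < T_PNG",
                       "DB_SOL < T_SOL", "DB_TS < T_TS")
  mk <- function(id, pap_parent, png_parent, sol_parent, extra_cond) {
    scenario(
      id = id, populations = pops, ne0 = ne0,
      events = c(base_events, list(
        list(kind = "split", pop = "PAP", parent = pap_parent,
             time = "T_PAP"),
        list(kind = "split", pop = "PNG", parent = png_parent,
             time = "T_PNG"),
        list(kind = "split", pop = "SOL", parent = sol_parent,
             time = "T_SOL"))),
      priors = priors,
      conditions = c(base_conditions, extra_cond),
      samples = samples, g_per_year = g, present = present)
  }
  out <- list(
    # s1 = s4 with the Solomons seeded from mainland SE Asia
    s1 = mk("s1", "SEA", "SEA", "SEA", character()),
    # alternative routes through New Guinea
    s2 = mk("s2", "SEA", "PAP", "PNG",
            c("T_PAP > T_PNG", "T_PNG > T_SOL")),
    s3 = mk("s3", "IDN", "SEA", "PNG", "T_PNG > T_SOL"),
    # best-supported route: both New Guinea introductions from SEA,
    # Solomons via PNG
    s4 = mk("s4", "SEA", "SEA", "PNG", "T_PNG > T_SOL"),
    s5 = mk("s5", "IDN", "IDN", "PNG", "T_PNG > T_SOL"))
  if (include_admixture) {
    pr6 <- c(priors, list(RA = prior_spec("uniform", 0.05, 0.95)))
    out$s6_admix <- scenario(
      id = "s6_admix", populations = pops, ne0 = ne0,
      events = c(base_events, list(
        list(kind = "split", pop = "PAP", parent = "SEA", time = "T_PAP"),
        list(kind = "split", pop = "PNG", parent = "SEA", time = "T_PNG"),
        list(kind = "admixture", pop = "SOL", parent = "SEA",
             parent2 = "PNG", prob = "RA", time = "T_SOL"))),
      priors = pr6,
      conditions = c(base_conditions, "T_PNG > T_SOL"),
      samples = samples, g_per_year = g, present = present)
  }
  out
}
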