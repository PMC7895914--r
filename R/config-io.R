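#' Configuration files and command-line entry point
#'
#' A run configuration is a YAML (or JSON) file with sections:
#'
#' ```yaml
#' game:        {M: 50, alpha: 0.02, r1: 0, r2: 1, r3: 2, c: 0}
#' distribution: {family: beta, params: [1, 5]}   # or uniform / empirical
#' solver:      {tol: 1e-10, grid: 999}
#' simulation:  {runs: 10000, seed: 7}
#' output:      {dir: "."}
#' ```
#'
#' Empirical distributions take `samples_file`, a single-column text/CSV
#' file with one posterior probability per line. Distributions can also be
#' given on the command line as compact specs such as `beta:0.5,0.5`,
#' `uniform:0,0.5` or `empirical:path.csv`.
#'
#' @name cli_io
#' @keywords internal
NULL

#' Parse a compact distribution specification
#'
#' @param spec String such as `"beta:1,5"`, `"uniform:0,0.5"` (or
#'   `"uniform"`), or `"empirical:samples.csv"`.
#' @return A [signal_dist] object.
#' @export
parse_dist_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  family <- parts[1]
  arg <- if (length(parts) > 1) parts[2] else ""
  switch(family,
    beta = {
      ps <- as.numeric(strsplit(arg, ",")[[1]])
      if (length(ps) != 2) stop("beta spec needs two parameters", call. = FALSE)
      signal_beta(ps[1], ps[2])
    },
    uniform = {
      if (!nzchar(arg)) return(signal_uniform())
      ps <- as.numeric(strsplit(arg, ",")[[1]])
      signal_uniform(ps[1], ps[2])
    },
    empirical = signal_empirical(read_posteriors(arg)),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

#' Read posterior probabilities from a one-column file
#' @param path Text or CSV file, one probability per line (a header line
#'   is tolerated).
#' @return Numeric vector.
#' @export
read_posteriors <- function(path) {
  if (!file.exists(path)) stop("samples file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, header = FALSE, sep = "",
                         stringsAsFactors = FALSE)[[1]]
  if (is.character(x)) x <- suppressWarnings(as.numeric(x[-1]))  # header row
  x <- x[!is.na(x)]
  if (!length(x)) stop("no numeric values in samples file", call. = FALSE)
  x
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, rejects unknown sections or
#' game keys, and materializes the package objects.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `cfg` (a [game_config]), `solver`,
#'   `simulation`, `output` and the raw parsed list.
#' @export
run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("game", "distribution", "solver", "simulation", "output")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  g <- raw$game %||% list()
  bad_keys <- setdiff(names(g), c("M", "alpha", "r1", "r2", "r3", "c"))
  if (length(bad_keys))
    stop("unknown game key(s): ", paste(bad_keys, collapse = ", "),
         call. = FALSE)
  M <- g$M %||% 50L
  params <- utility_params(r1 = g$r1 %||% 0, r2 = g$r2 %||% 1,
                           r3 = g$r3 %||% 2, c = g$c %||% 0,
                           alpha = g$alpha %||% (1 / M))
  d <- raw$distribution %||% list(family = "uniform")
  dist <- if (!is.null(d$samples_file)) {
    signal_empirical(read_posteriors(d$samples_file))
  } else {
    ps <- as.numeric(d$params %||% numeric())
    switch(d$family %||% "uniform",
           beta = signal_beta(ps[1], ps[2]),
           uniform = if (length(ps) >= 2) signal_uniform(ps[1], ps[2])
                     else signal_uniform(),
           empirical = stop("empirical family needs samples_file",
                            call. = FALSE),
           stop("unknown distribution family", call. = FALSE))
  }
  list(cfg = game_config(M, dist, params),
       solver = raw$solver %||% list(),
       simulation = raw$simulation %||% list(),
       output = raw$output %||% list(),
       raw = raw)
}

write_csv12 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Implements the `coarsegame` command-line tool (see
#' `inst/cli/coarsegame.R`). Subcommands: `static` (single-patient
#' threshold), `coarsen` (threshold profile and minimal stable threshold),
#' `solve` (MPE and/or social optimum), `simulate` (Monte Carlo), and
#' `cohort` (synthetic cohort pipeline). Run with `--help` after a
#' subcommand for its flags.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
coarsegame_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: coarsegame <static|coarsen|solve|simulate|cohort> [options]"
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- switch(cmd,
    static = cli_static(rest),
    coarsen = cli_coarsen(rest),
    solve = cli_solve(rest),
    simulate = cli_simulate(rest),
    cohort = cli_cohort(rest),
    { message("unknown subcommand: ", cmd, "\n", usage); 2L })
  invisible(status)
}

cli_static <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--e", type = "double", default = 1),
    optparse::make_option("--r1", type = "double", default = 0),
    optparse::make_option("--r2", type = "double", default = 0.5),
    optparse::make_option("--r3", type = "double", default = 1),
    optparse::make_option("--c", type = "double", default = 0.05),
    optparse::make_option("--alpha", type = "double", default = 0.05)
  )), args = args)
  params <- utility_params(opts$r1, opts$r2, opts$r3, opts$c, opts$alpha)
  cat(sprintf("treatment threshold T = %.6g\n",
              static_threshold(params, opts$e)))
  0L
}

cli_coarsen <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--dist", type = "character", default = "uniform"),
    optparse::make_option("--grid", type = "integer", default = 999L),
    optparse::make_option("--tmin-tol", dest = "tmin_tol", type = "double",
                          default = 1e-6),
    optparse::make_option("--out", type = "character", default = "profile.csv")
  )), args = args)
  dist <- parse_dist_spec(opts$dist)
  smax <- dist$support_max
  grid <- seq(smax / (opts$grid + 1), smax * opts$grid / (opts$grid + 1),
              length.out = opts$grid)
  prof <- threshold_profile(dist, grid)
  write_csv12(prof, opts$out)
  tmin <- min_stable_threshold(dist, tol = opts$tmin_tol)
  cat("minimal stable threshold:",
      if (is.na(tmin)) "none" else format(tmin, digits = 6), "\n")
  cat("profile written to", opts$out, "\n")
  0L
}

cli_solve <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--policy", type = "character", default = "both"),
    optparse::make_option("--out", type = "character", default = "policies.csv")
  )), args = args)
  rc <- run_config(opts$config)
  cfg <- rc$cfg
  out <- data.frame(k = seq_len(cfg$M))
  if (opts$policy %in% c("optimum", "both")) {
    so <- solve_social_optimum(cfg)
    out$d_opt <- so$thresholds; out$v_opt <- as.numeric(so$values)
  }
  if (opts$policy %in% c("mpe", "both")) {
    eq <- solve_mpe(cfg)
    out$d_mpe <- eq$thresholds; out$v_mpe <- as.numeric(eq$values)
  }
  write_csv12(out, opts$out)
  cat("policies written to", opts$out, "\n")
  0L
}

cli_simulate <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--policy1", type = "character", default = NULL),
    optparse::make_option("--policy2", type = "character", default = NULL),
    optparse::make_option("--runs", type = "integer", default = 10000L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "sim.csv")
  )), args = args)
  rc <- run_config(opts$config)
  cfg <- rc$cfg
  read_policy <- function(path) {
    if (is.null(path)) return(rep(0, cfg$M))
    df <- utils::read.csv(path)
    col <- intersect(c("d", "d_mpe", "d_opt"), names(df))[1]
    df[[col]]
  }
  sim <- simulate_game(read_policy(opts$policy1), read_policy(opts$policy2),
                       cfg, n_runs = opts$runs, seed = opts$seed)
  write_csv12(sim$runs, opts$out)
  print(sim)
  0L
}

cli_cohort <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--n", type = "integer", default = 1202L),
    optparse::make_option("--prevalence", type = "double",
                          default = 235 / 1202),
    optparse::make_option("--shape1", type = "double", default = 0.8),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = ".")
  )), args = args)
  rep <- cohort_pipeline(cohort_config(opts$n, opts$prevalence, opts$shape1,
                                       opts$seed))
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_csv12(rep$cohort, file.path(opts$out, "cohort.csv"))
  write_csv12(rep$profile, file.path(opts$out, "profile.csv"))
  jsonlite::write_json(
    list(n = rep$config$n, prevalence = rep$config$prevalence,
         E_p = rep$E_p, min_T = rep$min_T, min_T_true = rep$min_T_true),
    file.path(opts$out, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  print(rep)
  0L
}
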