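# Distribution-driven parameterization -----------------------------------
#
# Every tunable quantity can be a fixed value or a prior distribution,
# sampled per replicate (genome-wide layer) or per gene family, with
# family-level priors allowed to reference replicate-level draws as
# hyperparameters (e.g. a genome-wide duplication-rate mean shaping the
# across-family rate distribution).

DIST_FAMILIES <- c(F = 1L, U = 2L, N = 2L, LN = 2L, E = 1L, G = 2L)

#' Parse a distribution specification string
#'
#' Grammar (case-insensitive): `F:v` fixed, `U:a,b` uniform, `N:mean,sd`
#' normal, `LN:meanlog,sdlog` lognormal, `E:rate` exponential,
#' `G:shape,scale` gamma.  Operands are numbers or `$name` references to a
#' value sampled at an outer layer.  A bare number is shorthand for `F:x`.
#'
#' @param text The specification string.
#' @return A `dist_spec` object with fields `family` and `params` (each
#'   parameter either a numeric or a character reference name).
#' @export
parse_spec <- function(text) {
  if (inherits(text, "dist_spec")) return(text)
  if (is.numeric(text)) return(new_dist_spec("F", list(text)))
  s <- trimws(text)
  if (!grepl(":", s, fixed = TRUE)) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("cannot parse distribution spec: '", text, "'")
    return(new_dist_spec("F", list(v)))
  }
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  fam <- toupper(trimws(parts[1]))
  if (!fam %in% names(DIST_FAMILIES))
    stop("unknown distribution family '", parts[1], "' in spec '", text, "'")
  ops <- strsplit(paste(parts[-1], collapse = ":"), ",", fixed = TRUE)[[1]]
  ops <- trimws(ops)
  if (length(ops) != DIST_FAMILIES[[fam]])
    stop("distribution '", fam, "' expects ", DIST_FAMILIES[[fam]],
         " parameter(s), got ", length(ops), " in spec '", text, "'")
  params <- lapply(ops, function(o) {
    if (startsWith(o, "$")) return(substring(o, 2))
    v <- suppressWarnings(as.numeric(o))
    if (is.na(v)) stop("bad operand '", o, "' in spec '", text, "'")
    v
  })
  sp <- new_dist_spec(fam, params)
  # static constraint check when all operands are numeric
  if (!any(vapply(params, is.character, logical(1))))
    check_spec_constraints(sp, vapply(params, identity, numeric(1)), text)
  sp
}

new_dist_spec <- function(family, params) {
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  ops <- vapply(x$params, function(p)
    if (is.character(p)) paste0("$", p) else format(p), character(1))
  cat("dist_spec ", x$family, ":", paste(ops, collapse = ","), "\n", sep = "")
  invisible(x)
}

check_spec_constraints <- function(sp, v, text = "") {
  bad <- switch(sp$family,
    F = FALSE,
    U = v[1] >= v[2],
    N = v[2] <= 0,
    LN = v[2] <= 0,
    E = v[1] <= 0,
    G = v[1] <= 0 || v[2] <= 0)
  if (bad) stop("invalid parameters (", paste(v, collapse = ","),
                ") for distribution ", sp$family,
                if (nzchar(text)) paste0(" in spec '", text, "'"))
  invisible(TRUE)
}

#' Draw one value from a distribution specification
#'
#' `$name` references are resolved in `env`.  Normal draws for quantities
#' that must be positive can be truncated at zero by resampling
#' (`positive = TRUE`), capped at 1e4 attempts.
#'
#' @param spec A `dist_spec` (or a string, parsed on the fly).
#' @param env A named list/environment of previously sampled values used to
#'   resolve references.
#' @param positive Truncate at zero by resampling (Normal only; other
#'   families are either already positive or deliberately unrestricted).
#' @return A single numeric draw.
#' @export
sample_value <- function(spec, env = list(), positive = FALSE) {
  spec <- parse_spec(spec)
  v <- vapply(spec$params, function(p) {
    if (is.character(p)) {
      if (is.null(env[[p]]))
        stop("unresolved reference $", p, " in distribution spec")
      env[[p]]
    } else p
  }, numeric(1))
  check_spec_constraints(spec, v)
  draw <- function() switch(spec$family,
    F = v[1],
    U = stats::runif(1, v[1], v[2]),
    N = stats::rnorm(1, v[1], v[2]),
    LN = stats::rlnorm(1, v[1], v[2]),
    E = stats::rexp(1, v[1]),
    G = stats::rgamma(1, shape = v[1], scale = v[2]))
  x <- draw()
  if (positive && spec$family == "N") {
    tries <- 0L
    while (x <= 0 && tries < 1e4) { x <- draw(); tries <- tries + 1L }
    if (x <= 0) stop("failed to draw a positive value from Normal(",
                     v[1], ",", v[2], ") after 1e4 attempts")
  }
  x
}

is_fixed_spec <- function(spec) parse_spec(spec)$family == "F"

# Deterministic RNG substreams --------------------------------------------
# Each (replicate, family, purpose) unit gets its own seed derived from the
# master seed by integer hashing, so draws are reproducible regardless of
# execution order and of how many draws other units consume.

substream_seed <- function(master, ...) {
  ids <- c(master, ...)
  h <- 0
  for (x in ids) {
    # numeric-safe 31-bit multiplicative mixing
    h <- (h * 69069 + (as.numeric(x) %% 2147483647) + 1) %% 2147483647
    h <- (h * 48271) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(master, ..., expr) {
  seed <- substream_seed(master, ...)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Layered resolution ------------------------------------------------------

REPLICATE_KEYS <- c("speciation_rate", "extinction_rate", "n_taxa", "height",
                    "outgroup", "ne", "individuals", "subst_rate", "gen_time",
                    "n_families", "alpha_species", "alpha_family", "alpha_gene",
                    "dup_hyper", "loss_hyper", "hgt_hyper", "conv_hyper")
FAMILY_KEYS <- c("dup_rate", "loss_rate", "hgt_rate", "conv_rate")
POSITIVE_KEYS <- c("speciation_rate", "height", "ne", "subst_rate", "gen_time",
                   "alpha_species", "alpha_family", "alpha_gene")

#' Sample the hierarchical parameter layers for one replicate
#'
#' Replicate-level (genome-wide) parameters are drawn once; family-level
#' rates are then drawn once per family from specifications that may
#' reference replicate-level values with `$name` (the replicate value acts
#' as a hyperparameter).  Each unit uses an independent, order-insensitive
#' RNG substream keyed by (seed, replicate, family).
#'
#' @param config A named list of specification strings / numbers (see
#'   [sim_config()] for recognized keys).
#' @param seed Master integer seed.
#' @param replicate Replicate index (1-based).
#' @return A list with `replicate` (named numeric values), `families`
#'   (data.frame of per-family rates) and `provenance` (which spec produced
#'   which value).
#' @export
resolve_layers <- function(config, seed, replicate = 1L) {
  rep_vals <- list()
  prov <- list()
  with_substream(seed, replicate, 0L, expr = {
    for (key in REPLICATE_KEYS) {
      if (is.null(config[[key]])) next
      sp <- parse_spec(config[[key]])
      # forbid sideways references at replicate level except to earlier keys
      val <- sample_value(sp, env = rep_vals, positive = key %in% POSITIVE_KEYS)
      rep_vals[[key]] <- val
      prov[[key]] <- config[[key]]
    }
  })
  nf <- max(1L, as.integer(round(rep_vals$n_families %||% 1)))
  fam <- matrix(0, nrow = nf, ncol = length(FAMILY_KEYS),
                dimnames = list(NULL, FAMILY_KEYS))
  for (f in seq_len(nf)) {
    with_substream(seed, replicate, f, expr = {
      for (key in FAMILY_KEYS) {
        sp <- config[[key]] %||% "F:0"
        fam[f, key] <- sample_value(parse_spec(sp), env = rep_vals)
        if (fam[f, key] < 0) stop("negative sampled rate for ", key)
      }
    })
  }
  list(replicate = rep_vals, families = as.data.frame(fam),
       provenance = prov, seed = seed, replicate_index = replicate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a simulation configuration
#'
#' Any value may be a number (fixed) or a distribution-spec string.
#' Family-level rate specs (`dup_rate`, `loss_rate`, `hgt_rate`,
#' `conv_rate`) may reference replicate-level keys via `$name`.
#'
#' @param n_replicates Number of replicates.
#' @param n_families Families (gene trees) per replicate.
#' @param speciation_rate,extinction_rate Species birth/death rates per
#'   time unit.
#' @param n_taxa Extant species count (switches the species simulator to
#'   tip-count conditioning); `NULL` to condition on `height` alone.
#' @param height Tree origin time (time units).
#' @param outgroup Relative outgroup distance (`NULL` for none).
#' @param ne Effective population size per branch.
#' @param individuals Sampled individuals per species.
#' @param subst_rate Substitutions/site/generation.
#' @param gen_time Generations per time unit (`NULL` = 1).
#' @param dup_rate,loss_rate,hgt_rate,conv_rate Per-generation locus rates.
#' @param alpha_species,alpha_family,alpha_gene Gamma shapes of the three
#'   mean-one rate-multiplier layers (`NULL` disables a layer).
#' @param receptor_mode `"uniform"` or `"inverse_distance"` receptor choice
#'   for transfers/conversions.
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param lost_policy `"keep-empty"` or `"resample"` for fully lost families.
#' @param dup_hyper,loss_hyper,hgt_hyper,conv_hyper Optional replicate-level
#'   hyperparameter specs referenced by the family-level rate specs.
#' @return A named list (class `sim_config`).
#' @export
sim_config <- function(n_replicates = 1, n_families = 1,
                       speciation_rate = 1e-6, extinction_rate = 0,
                       n_taxa = NULL, height = NULL, outgroup = NULL,
                       ne = 10000, individuals = 1, subst_rate = 1e-8,
                       gen_time = NULL,
                       dup_rate = 0, loss_rate = 0, hgt_rate = 0, conv_rate = 0,
                       alpha_species = NULL, alpha_family = NULL,
                       alpha_gene = NULL,
                       receptor_mode = c("uniform", "inverse_distance"),
                       ploidy = 1, lost_policy = c("keep-empty", "resample"),
                       dup_hyper = NULL, loss_hyper = NULL, hgt_hyper = NULL,
                       conv_hyper = NULL) {
  cfg <- list(n_replicates = n_replicates, n_families = n_families,
              speciation_rate = speciation_rate,
              extinction_rate = extinction_rate,
              n_taxa = n_taxa, height = height, outgroup = outgroup,
              ne = ne, individuals = individuals, subst_rate = subst_rate,
              gen_time = gen_time,
              dup_rate = dup_rate, loss_rate = loss_rate,
              hgt_rate = hgt_rate, conv_rate = conv_rate,
              alpha_species = alpha_species, alpha_family = alpha_family,
              alpha_gene = alpha_gene,
              receptor_mode = match.arg(receptor_mode),
              ploidy = ploidy, lost_policy = match.arg(lost_policy),
              dup_hyper = dup_hyper, loss_hyper = loss_hyper,
              hgt_hyper = hgt_hyper, conv_hyper = conv_hyper)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  if (is.null(cfg$n_taxa) && is.null(cfg$height))
    stop("one of n_taxa or height must be given")
  structure(cfg, class = "sim_config")
}

#' Read a configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are
#' distribution-spec strings or numbers.
#'
#' @param path Path to the configuration file.
#' @return A `sim_config` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("bad config line (no '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  do.call(sim_config, kv)
}
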