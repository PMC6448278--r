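#' @useDynLib protoworld, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom runif
#' @importFrom utils read.csv write.csv modifyList
NULL

# Master table of the parameter system: name, kind, default, and the
# magnitude range explored in the underlying study (stored as metadata only;
# no sampling scheme is attached to it).
.param_defs <- function() {
  p <- function(name, default, lo, hi, desc) {
    data.frame(name = name, kind = "prob", default = default, lo = lo, hi = hi,
               desc = desc, stringsAsFactors = FALSE)
  }
  o <- function(name, kind, default, lo, hi, desc) {
    data.frame(name = name, kind = kind, default = default, lo = lo, hi = hi,
               desc = desc, stringsAsFactors = FALSE)
  }
  rbind(
    p("P_AT",  0.4,    0.3,   0.5,    "template attracting a substrate by base-pairing"),
    p("P_BB",  2e-6,   1e-6,  5e-6,   "phosphodiester bond breaking within an RNA chain"),
    p("P_FLR", 0.1,    0.05,  0.2,    "false ligation under REP catalysis"),
    p("P_FP",  1e-4,   5e-5,  2e-4,   "false base-pairing when a template attracts a substrate"),
    p("P_MV",  1e-4,   5e-5,  2e-4,   "movement of nucleotides/amphiphiles or their precursors"),
    p("P_ND",  0.005,  0.002, 0.01,   "a nucleotide decaying into its precursor"),
    p("P_NDE", 2e-4,   1e-4,  5e-4,   "a nucleotide residue decaying at a chain end"),
    p("P_NF",  2e-4,   1e-4,  5e-4,   "nucleotide forming from its precursor (non-enzymatic)"),
    p("P_NFR", 0.9,    0.5,   0.9,    "nucleotide forming from its precursor, NSR-catalyzed"),
    p("P_RBT", 0.4,    0.3,   0.5,    "a REP binding onto a tagged template"),
    p("P_RD",  1e-4,   5e-5,  2e-4,   "a REP dropping from a template"),
    p("P_RL",  1e-6,   5e-7,  2e-6,   "random ligation of two RNAs (including nucleotides)"),
    p("P_RTT", 0.5,    0.4,   0.6,    "an RNA turning to a template (non-enzymatic synthesis)"),
    p("P_SP",  0.38,   0.3,   0.4,    "separation of a base pair"),
    p("P_TL",  1e-4,   5e-5,  2e-4,   "template-directed ligation (non-enzymatic)"),
    p("P_TLR", 0.9,    0.5,   0.9,    "template-directed ligation, REP-catalyzed"),
    p("P_AD",  2e-4,   1e-4,  5e-4,   "an amphiphile decaying (out of membrane)"),
    p("P_ADM", 2e-5,   1e-5,  5e-5,   "an amphiphile decaying within a membrane"),
    p("P_AF",  0.001,  5e-4,  0.002,  "an amphiphile forming from its precursor"),
    p("P_AJM", 0.8,    0.7,   0.9,    "an amphiphile joining a membrane"),
    p("P_ALM", 2e-4,   1e-4,  5e-4,   "an amphiphile leaving a membrane"),
    p("P_APP", 1,      0.5,   1,      "an amphiphile precursor permeating a membrane"),
    p("P_CB",  1e-5,   5e-6,  2e-5,   "a protocell breaking"),
    p("P_CC",  1e-7,   1e-7,  5e-7,   "a protocell engulfing molecules (cytophagy)"),
    p("P_CD",  1e-4,   5e-5,  2e-4,   "a protocell dividing"),
    p("P_CF",  0.005,  0.002, 0.01,   "two adjacent protocells fusing"),
    p("P_MC",  1e-5,   5e-6,  2e-5,   "movement of a protocell"),
    p("P_MF",  0.01,   0.005, 0.02,   "a membrane forming"),
    p("P_NPP", 0.1,    0.05,  0.2,    "a nucleotide precursor permeating a membrane"),
    o("N",     "count", 40,     20,    40,     "grid side of the N x N system"),
    o("T_NPB", "count", 320000, 80000, 320000, "total nucleotide precursors at the start"),
    o("T_APB", "count", 240000, 60000, 240000, "total amphiphile precursors at the start"),
    o("F_OP",  "factor", 10,    5,     10,     "factor for the osmotic-pressure effect"),
    o("F_DE",  "factor", 10,    5,     10,     "factor for the Donnan-equilibrium effect"),
    o("C_T",   "count", 8,      5,     10,     "collision rounds per Monte Carlo step"),
    o("L_AM",  "count", 500,    400,   600,    "lower limit of amphiphiles to form a membrane")
  )
}

.seq_defaults <- function() {
  list(CS_REP = "CUCGACAGAU", CS_NSR = "ACUGGCAUCU", CS_Tag = "ACGU")
}

# Ordering relations the defaults are expected to respect; violations are
# reported as warnings only, so parameter sweeps may deliberately cross them.
.param_orderings <- list(
  c("P_TLR", ">", "P_TL"),  c("P_NFR", ">", "P_NF"), c("P_TL", ">", "P_RL"),
  c("P_NDE", "<", "P_ND"),  c("P_ADM", "<", "P_AD"), c("P_MF", ">", "P_CB"),
  c("P_AJM", ">", "P_ALM"), c("P_MV",  ">", "P_MC"), c("P_APP", ">", "P_NPP")
)

#' Parameter metadata table
#'
#' Returns the full catalogue of simulation parameters: name, kind
#' (`prob`, `count`, `factor`), default value, the magnitude range explored
#' in the study (metadata only), and a one-line description. Sequence
#' parameters (`CS_REP`, `CS_NSR`, `CS_Tag`) are listed with `kind = "seq"`.
#'
#' @return A data frame with columns `name`, `kind`, `default`, `lo`, `hi`,
#'   `desc`.
#' @export
param_table <- function() {
  num <- .param_defs()
  sq <- .seq_defaults()
  seqs <- data.frame(name = names(sq), kind = "seq", default = NA_real_,
                     lo = NA_real_, hi = NA_real_,
                     desc = c("catalytic-domain sequence of REP",
                              "catalytic-domain sequence of NSR",
                              "palindromic tag sequence"),
                     stringsAsFactors = FALSE)
  rbind(num, seqs)
}

#' Default parameter set
#'
#' All event probabilities and system constants at their default values,
#' plus the default catalytic-domain and tag sequences.
#'
#' @return An object of class `rw_params`: a named list with one element per
#'   parameter.
#' @export
default_params <- function() {
  defs <- .param_defs()
  p <- as.list(defs$default)
  names(p) <- defs$name
  p <- c(p, .seq_defaults())
  class(p) <- "rw_params"
  p
}

#' Validate a parameter set
#'
#' Checks ranges (probabilities in \[0,1\], counts >= 1, factors > 0),
#' alphabet and palindromy of the tag sequence, and the expected ordering
#' relations between rates (catalyzed much faster than non-enzymatic,
#' membrane-protected decay slower than free decay, and so on). Range and
#' alphabet violations are errors; ordering violations are warnings, so that
#' deliberate sweeps may cross them.
#'
#' @param p An `rw_params` object (see [default_params()]).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  defs <- .param_defs()
  for (i in seq_len(nrow(defs))) {
    nm <- defs$name[i]
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("parameter %s is missing or not a single number", nm))
    if (defs$kind[i] == "prob" && (v < 0 || v > 1))
      stop(sprintf("%s out of [0,1]", nm))
    if (defs$kind[i] == "count" && (v < 1 || v != round(v)))
      stop(sprintf("%s must be an integer count >= 1", nm))
    if (defs$kind[i] == "factor" && v <= 0)
      stop(sprintf("%s must be > 0", nm))
  }
  for (nm in names(.seq_defaults())) {
    s <- p[[nm]]
    if (is.null(s) || !is.character(s) || length(s) != 1L || nchar(s) < 1L)
      stop(sprintf("%s must be a non-empty RNA sequence", nm))
    if (grepl("[^ACGU]", s))
      stop(sprintf("%s contains symbols outside {A,C,G,U}", nm))
  }
  if (reverse_complement(p$CS_Tag) != p$CS_Tag)
    stop("tag not palindromic: CS_Tag must equal its own reverse complement")
  for (ord in .param_orderings) {
    a <- p[[ord[1]]]; b <- p[[ord[3]]]
    ok <- if (ord[2] == ">") a > b else a < b
    if (!ok)
      warning(sprintf("ordering %s %s %s violated (%g vs %g)",
                      ord[1], ord[2], ord[3], a, b), call. = FALSE)
  }
  invisible(p)
}

#' Load a parameter set from a config file or override list
#'
#' Reads a plain-text configuration (sections `[parameters]`,
#' `[regions.rocky]`, `[regions.solution]`, `[scenario]`; `key = value`
#' lines; `#` comments). Omitted parameters take their defaults; unknown keys
#' are an error, so typos in sweep scripts fail loudly.
#'
#' @param path Path to a config file, or `NULL` to use defaults.
#' @param overrides A named list applied on top of the file (or defaults).
#' @return An `rw_params` object. Region and scenario sections, when present,
#'   are attached as attributes `regions` and `scenario`.
#' @export
load_parameters <- function(path = NULL, overrides = list()) {
  p <- default_params()
  regions <- NULL
  scenario <- NULL
  if (!is.null(path)) {
    cfg <- .parse_config(path)
    known <- names(p)
    for (nm in names(cfg$parameters)) {
      if (!nm %in% known) stop(sprintf("unknown parameter key '%s'", nm))
      p[[nm]] <- cfg$parameters[[nm]]
    }
    regions <- cfg$regions
    scenario <- cfg$scenario
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop(sprintf("unknown parameter key '%s'", bad[1]))
    p[names(overrides)] <- overrides
  }
  class(p) <- "rw_params"
  validate_params(p)
  if (!is.null(regions)) attr(p, "regions") <- regions
  if (!is.null(scenario)) attr(p, "scenario") <- scenario
  p
}

# key = value config parser with [section] headers.
.parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(parameters = list(), regions = list(), scenario = list())
  section <- "parameters"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else if (val %in% c("true", "false")) {
      val == "true"
    } else val
    if (section == "parameters") {
      out$parameters[[key]] <- parsed
    } else if (grepl("^regions\\.", section)) {
      lab <- sub("^regions\\.", "", section)
      out$regions[[lab]][[key]] <- parsed
    } else if (section == "scenario") {
      out$scenario[[key]] <- parsed
    } else {
      stop(sprintf("unknown config section '[%s]'", section))
    }
  }
  out
}

#' Serialize a parameter set to config format
#'
#' Writes (or returns) the flat `key = value` representation read back by
#' [load_parameters()]; the round trip is field-wise exact.
#'
#' @param p An `rw_params` object.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return The config lines, invisibly when written to a file.
#' @export
write_config <- function(p, path = NULL) {
  defs <- .param_defs()
  fmt <- function(v) {
    if (is.character(v)) v else format(v, scientific = FALSE, digits = 17)
  }
  lines <- c("[parameters]",
             vapply(c(defs$name, names(.seq_defaults())),
                    function(nm) sprintf("%s = %s", nm, fmt(p[[nm]])), ""))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Region profile
#'
#' A region of the grid (`rocky` or `solution`) modifies the base rates:
#' movement (`P_MV`) by `mv_mult`, degradation rates (`P_BB`, `P_ND`,
#' `P_NDE`, `P_AD`) by `degr_mult`, and synthesis rates (`P_RL`, `P_NF`) by
#' `syn_mult`. Degradation multipliers never apply inside a protocell, whose
#' interior is not a free-water environment. Protocells can exist only where
#' `protocells_allowed` is true (they cannot enter the rocky region).
#'
#' @param label `"rocky"` or `"solution"`.
#' @param mv_mult,degr_mult,syn_mult Positive multipliers.
#' @param protocells_allowed Logical.
#' @return An `rw_region` object.
#' @export
region_profile <- function(label, mv_mult = 1, degr_mult = 1, syn_mult = 1,
                           protocells_allowed = (label == "solution")) {
  stopifnot(label %in% c("rocky", "solution"))
  if (any(c(mv_mult, degr_mult, syn_mult) <= 0))
    stop("region multipliers must be > 0")
  structure(list(label = label, mv_mult = mv_mult, degr_mult = degr_mult,
                 syn_mult = syn_mult,
                 protocells_allowed = isTRUE(protocells_allowed)),
            class = "rw_region")
}

#' Default region profiles
#'
#' The rocky region runs at base rates (identity multipliers). The solution
#' region — free water surrounding the porous-rock core — has molecular
#' movement ten times faster, degradation rates (`P_BB`, `P_ND`, `P_NDE`,
#' `P_AD`) twice as fast (outside protocells only), and synthesis rates
#' (`P_RL`, `P_NF`) one twentieth, reflecting the loss of surface-mediated
#' catalysis.
#'
#' @param near_reality If `FALSE`, the solution profile is made identical to
#'   the rocky one (used in "fair competition" setups where the membrane is
#'   the only difference between the subsystems).
#' @return A list with elements `rocky` and `solution`.
#' @export
default_region_profiles <- function(near_reality = TRUE) {
  if (near_reality) {
    list(rocky = region_profile("rocky"),
         solution = region_profile("solution", mv_mult = 10, degr_mult = 2,
                                   syn_mult = 1 / 20))
  } else {
    list(rocky = region_profile("rocky"),
         solution = region_profile("solution"))
  }
}

.DEGR_PARAMS <- c("P_BB", "P_ND", "P_NDE", "P_AD")
.SYN_PARAMS <- c("P_RL", "P_NF")

#' Apply a region profile to a parameter set
#'
#' Returns the effective parameter set in a given region, inside or outside a
#' protocell. Movement and synthesis multipliers always apply; degradation
#' multipliers are skipped inside a protocell. Multiplied probabilities are
#' clamped to \[0,1\].
#'
#' @param base An `rw_params` object.
#' @param region An `rw_region` object.
#' @param inside_protocell Logical.
#' @return An `rw_params` object with effective values.
#' @export
effective_params <- function(base, region, inside_protocell = FALSE) {
  stopifnot(inherits(region, "rw_region"))
  eff <- base
  clamp <- function(x) min(max(x, 0), 1)
  eff$P_MV <- clamp(base$P_MV * region$mv_mult)
  for (nm in .SYN_PARAMS) eff[[nm]] <- clamp(base[[nm]] * region$syn_mult)
  if (!inside_protocell) {
    for (nm in .DEGR_PARAMS) eff[[nm]] <- clamp(base[[nm]] * region$degr_mult)
  }
  eff
}

#' @export
print.rw_params <- function(x, ...) {
  cat("<rw_params> ", length(x), " parameters\n", sep = "")
  defs <- .param_defs()
  changed <- defs$name[vapply(defs$name,
                              function(nm) x[[nm]] != defs$default[defs$name == nm],
                              logical(1))]
  if (length(changed)) {
    cat("non-default:", paste(sprintf("%s=%g", changed,
                                      unlist(x[changed])), collapse = ", "), "\n")
  } else {
    cat("all numeric parameters at defaults\n")
  }
  cat(sprintf("CS_REP=%s CS_NSR=%s CS_Tag=%s\n", x$CS_REP, x$CS_NSR, x$CS_Tag))
  invisible(x)
}
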