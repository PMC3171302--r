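#' Delay specification for a delayed reaction product
#'
#' Delayed products are held on the simulator's waitlist and released after a
#' delay drawn from this specification. Two kinds are supported: a constant
#' (deterministic) delay and a Gaussian delay. Gaussian draws that come out
#' negative are redrawn, so realised delays are always nonnegative.
#'
#' @param mean Mean delay in seconds (the exact delay for `kind = "constant"`).
#' @param sd Standard deviation in seconds; must be 0 for constant delays.
#' @param kind Either `"constant"` or `"gaussian"`.
#' @return An object of class `delay_spec`.
#' @examples
#' delay_spec(40)                  # constant 40 s
#' delay_spec(102, 14, "gaussian") # RNA completion delay
#' @export
delay_spec <- function(mean, sd = 0, kind = if (sd > 0) "gaussian" else "constant") {
  kind <- match.arg(kind, c("constant", "gaussian"))
  if (!is.numeric(mean) || length(mean) != 1L || mean < 0)
    stop("delay mean must be a single nonnegative number")
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
    stop("delay sd must be a single nonnegative number")
  if (kind == "constant" && sd != 0)
    stop("constant delays must have sd = 0")
  structure(list(kind = kind, mean = mean, sd = sd), class = "delay_spec")
}

#' @export
print.delay_spec <- function(x, ...) {
  if (x$kind == "constant") cat(sprintf("<delay: constant %g s>\n", x$mean))
  else cat(sprintf("<delay: Gaussian(mean %g s, sd %g s), negatives redrawn>\n", x$mean, x$sd))
  invisible(x)
}

#' Define a (possibly delayed) reaction channel
#'
#' A reaction consumes its reactants instantaneously when it fires, releases
#' its instantaneous products at the firing time, and places each delayed
#' product on the waitlist with an absolute release time equal to the firing
#' time plus a delay drawn from the product's [delay_spec()].
#'
#' @param reactants Named integer vector of reactant stoichiometries
#'   (may be empty for a constitutive reaction).
#' @param products Named integer vector of instantaneous product
#'   stoichiometries (may be empty).
#' @param delayed List of delayed products, each a list with elements
#'   `species` (name), `count` (positive integer) and `delay` (a
#'   [delay_spec()]).
#' @param rate Stochastic rate constant, per second, nonnegative.
#' @param name Optional channel label used in printouts.
#' @return An object of class `reaction`.
#' @examples
#' reaction(c(RNA = 1), rate = 1 / 600, name = "degradation")
#' @export
reaction <- function(reactants = integer(), products = integer(),
                     delayed = list(), rate, name = NULL) {
  if (is.null(reactants)) reactants <- integer()
  if (is.null(products)) products <- integer()
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("rate constant must be a single nonnegative number")
  check_stoich <- function(v, what) {
    if (length(v) == 0L) return(invisible())
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop(what, " must be a named vector")
    if (any(v != as.integer(v)) || any(v < 1))
      stop(what, " stoichiometries must be positive integers")
  }
  check_stoich(reactants, "reactants")
  check_stoich(products, "products")
  for (d in delayed) {
    if (!is.list(d) || !all(c("species", "count", "delay") %in% names(d)))
      stop("each delayed product needs fields species, count, delay")
    if (!inherits(d$delay, "delay_spec")) stop("delay must be a delay_spec")
    if (d$count != as.integer(d$count) || d$count < 1)
      stop("delayed product count must be a positive integer")
  }
  structure(list(reactants = as.integer(round(reactants)) |> stats::setNames(names(reactants)),
                 products = as.integer(round(products)) |> stats::setNames(names(products)),
                 delayed = delayed, rate = rate, name = name),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  side <- function(v) if (length(v) == 0L) "∅"
    else paste(ifelse(v > 1, paste0(v, " "), ""), names(v), sep = "", collapse = " + ")
  del <- vapply(x$delayed, function(d) {
    tag <- if (d$delay$kind == "constant") sprintf("%g s", d$delay$mean)
           else sprintf("N(%g, %g) s", d$delay$mean, d$delay$sd)
    paste0(if (d$count > 1) paste0(d$count, " ") else "", d$species, " (", tag, ")")
  }, character(1))
  rhs <- c(if (length(x$products)) side(x$products), del)
  cat(sprintf("%s%s --[%g /s]--> %s\n",
              if (is.null(x$name)) "" else paste0(x$name, ": "),
              side(x$reactants), x$rate,
              if (length(rhs)) paste(rhs, collapse = " + ") else "∅"))
  invisible(x)
}

#' Assemble reactions into a simulatable system
#'
#' @param reactions List of [reaction()] objects.
#' @param initial_counts Named integer vector of initial molecule counts;
#'   species not mentioned by any reaction may be included.
#' @return An object of class `reaction_system` with elements `species`,
#'   `reactions` and `initial_counts`.
#' @export
reaction_system <- function(reactions, initial_counts) {
  if (!length(reactions) || !all(vapply(reactions, inherits, logical(1), "reaction")))
    stop("reactions must be a nonempty list of reaction objects")
  sp <- unique(c(names(initial_counts),
                 unlist(lapply(reactions, function(r)
                   c(names(r$reactants), names(r$products),
                     vapply(r$delayed, `[[`, character(1), "species"))))))
  init <- stats::setNames(integer(length(sp)), sp)
  init[names(initial_counts)] <- as.integer(initial_counts)
  if (any(init < 0)) stop("initial counts must be nonnegative")
  structure(list(species = sp, reactions = reactions, initial_counts = init),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("Reaction system: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  cat("Initial counts:",
      paste(sprintf("%s = %d", names(x$initial_counts), x$initial_counts), collapse = ", "),
      "\n")
  for (r in x$reactions) print(r)
  invisible(x)
}

# Compile a reaction_system into the 0-indexed integer form the C++ engine
# and the R reference stepper both consume.
compile_system <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  idx <- stats::setNames(seq_along(system$species) - 1L, system$species)
  lapply(system$reactions, function(r) {
    list(react_sp = unname(idx[names(r$reactants)]),
         react_n = unname(r$reactants),
         inst_sp = unname(idx[names(r$products)]),
         inst_n = unname(r$products),
         del_sp = vapply(r$delayed, function(d) unname(idx[d$species]), integer(1)),
         del_n = vapply(r$delayed, function(d) as.integer(d$count), integer(1)),
         del_kind = vapply(r$delayed, function(d) if (d$delay$kind == "gaussian") 1L else 0L, integer(1)),
         del_mean = vapply(r$delayed, function(d) d$delay$mean, numeric(1)),
         del_sd = vapply(r$delayed, function(d) d$delay$sd, numeric(1)),
         rate = r$rate)
  })
}

#' Read a reaction system from a YAML model definition
#'
#' The file lists `species` with initial counts and `reactions`, each with
#' optional `reactants`, `products` (name: stoichiometry mappings), optional
#' `delayed` products (`species`, `count`, `delay: {mean, sd, kind}`) and a
#' `rate`.
#'
#' @param path Path to the YAML file.
#' @return A [reaction_system()].
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || is.null(cfg$reactions))
    stop("model YAML needs 'species' and 'reactions'")
  rx <- lapply(cfg$reactions, function(r) {
    delayed <- lapply(r$delayed %||% list(), function(d)
      list(species = d$species, count = d$count %||% 1L,
           delay = delay_spec(d$delay$mean, d$delay$sd %||% 0,
                              d$delay$kind %||% if ((d$delay$sd %||% 0) > 0) "gaussian" else "constant")))
    reaction(reactants = unlist(r$reactants %||% list()),
             products = unlist(r$products %||% list()),
             delayed = delayed, rate = r$rate, name = r$name %||% NULL)
  })
  reaction_system(rx, unlist(cfg$species))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
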