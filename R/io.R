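#' Bit-exact JSON serialization of domain objects
#'
#' All structured input and output uses JSON in which every rational is a
#' `"p/q"` string, never a float, so that serialization round-trips are
#' bit-exact. `object_to_list()` converts a domain object into a plain
#' list of strings (plus a `type` tag); `object_from_list()` inverts it.
#' `parse(emit(x))` reproduces `x` exactly for every supported type.
#'
#' Supported types: [lv_system] (`"system"`), [lv_solution]
#' (`"solution"`), [lv_aux] (`"aux"`), [lv_riccati] (`"riccati"`),
#' [lv_pair] (`"pair"`), [condition_report] (`"report"`).
#'
#' @param x a domain object.
#' @return `object_to_list`: a named list of strings/lists;
#'   `object_from_list`: the reconstructed domain object.
#' @export
object_to_list <- function(x) {
  ch <- function(v) as.character(bigq(v))
  if (inherits(x, "lv_system")) {
    out <- lapply(unclass(x), ch)
    return(c(list(type = "system"), out))
  }
  if (inherits(x, "lv_solution")) {
    return(list(
      type = "solution", n = x$n, eta = ch(x$eta), t0 = ch(x$t0),
      sigmas = ch(x$sigmas), aes = ch(x$aes),
      ratios = lapply(x$components, function(cmp) ch(cmp$ratios))))
  }
  if (inherits(x, "lv_aux")) {
    out <- lapply(unclass(x)[setdiff(names(x), c("n", "A2"))], ch)
    return(c(list(type = "aux", n = x$n), out))
  }
  if (inherits(x, "lv_riccati")) {
    return(list(type = "riccati", c0 = ch(x$c0), c1 = ch(x$c1),
                c2 = ch(x$c2)))
  }
  if (inherits(x, "lv_pair")) {
    return(list(type = "pair", a = ch(x$a), b = ch(x$b)))
  }
  if (inherits(x, "condition_report")) {
    return(list(
      type = "report", pass = x$pass,
      guards_violated = as.list(x$guards_violated),
      residuals = lapply(x$residuals, function(r) {
        if (is_bigq(r)) as.character(r) else as.numeric(r)
      })))
  }
  stop("no serializer for class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' @rdname object_to_list
#' @param lst a list produced by `object_to_list` (or parsed back from its
#'   JSON form).
#' @export
object_from_list <- function(lst) {
  type <- lst$type
  if (is.null(type)) stop("missing 'type' tag", call. = FALSE)
  uv <- function(v) unlist(v, use.names = FALSE)
  switch(type,
    system = lv_system(a0 = uv(lst$a0), a1 = uv(lst$a1), a2 = uv(lst$a2),
                       lambda = uv(lst$lambda), b0 = uv(lst$b0),
                       b1 = uv(lst$b1), b2 = uv(lst$b2), mu = uv(lst$mu),
                       gamma = uv(lst$gamma)),
    solution = lv_solution(n = as.integer(lst$n), eta = uv(lst$eta),
                           t0 = uv(lst$t0), sigmas = bigq(uv(lst$sigmas)),
                           aes = bigq(uv(lst$aes)),
                           ratios = lapply(lst$ratios, uv)),
    aux = lv_aux(n = as.integer(lst$n), A1 = uv(lst$A1),
                 L1 = uv(lst$L1), L2 = uv(lst$L2), L3 = uv(lst$L3),
                 N1 = uv(lst$N1), N2 = uv(lst$N2), N3 = uv(lst$N3),
                 K1 = uv(lst$K1), K2 = uv(lst$K2), K3 = uv(lst$K3)),
    riccati = lv_riccati(uv(lst$c0), uv(lst$c1), uv(lst$c2)),
    pair = lv_pair(a = uv(lst$a), b = uv(lst$b)),
    report = condition_report(
      residuals = lapply(lst$residuals, function(r) {
        if (is.character(uv(r))) bigq(uv(r)) else as.numeric(uv(r))
      }),
      guards_violated = as.character(uv(lst$guards_violated))),
    stop("unknown object type '", type, "'", call. = FALSE)
  )
}

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0L) {
    x <- x[order(names(x))]
    return(lapply(x, sort_keys))
  }
  if (is.list(x)) return(lapply(x, sort_keys))
  x
}

#' Deterministic key-sorted JSON emission
#'
#' Writes any result (a domain object, a [condition_report], or a plain
#' list of such) to a JSON file with recursively sorted keys, so identical
#' inputs always produce byte-identical files. Domain objects are
#' converted through [object_to_list()]; rationals are emitted as `"p/q"`
#' strings.
#'
#' @param result the object to write.
#' @param path output file path (or `""` for standard output).
#' @return `path`, invisibly.
#' @export
emit_report <- function(result, path) {
  to_plain <- function(x) {
    if (inherits(x, c("lv_system", "lv_solution", "lv_aux", "lv_riccati",
                      "lv_pair", "condition_report"))) {
      return(lapply(object_to_list(x), to_plain))
    }
    if (is_bigq(x)) return(as.character(x))
    if (inherits(x, "qpoly")) return(as.character(x$coef))
    if (is.list(x)) return(lapply(x, to_plain))
    x
  }
  js <- jsonlite::toJSON(sort_keys(to_plain(result)), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null",
                         na = "null")
  if (identical(path, "")) cat(js, "\n", sep = "") else writeLines(js, path)
  invisible(path)
}

config_schema <- list(
  kink = list(required = c("c0", "c1", "c2"), optional = c("x_init")),
  `pair-check` = list(required = c("a", "b"), optional = character(0)),
  construct = list(required = c("order", "fixed", "aes", "sigmas", "eta",
                                "t0"),
                   optional = c("zero_aes", "branch")),
  invert = list(required = c("order", "system"),
                optional = c("gauge", "zero_aes")),
  verify = list(required = c("system", "solution"),
                optional = c("aux")),
  fixture = list(required = c("order", "seed"),
                 optional = c("max_abs", "max_tries")),
  simulate = list(required = c("system", "solution", "t_start", "t_end"),
                  optional = c("n_grid", "rtol"))
)

check_rationals <- function(x, key = "") {
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      check_rationals(x[[i]], if (is.null(nms) || nms[i] == "") key
                              else nms[i])
    }
    return(invisible(NULL))
  }
  if (is.numeric(x) && any(is.finite(x) & x != round(x))) {
    stop("float literal ", x[x != round(x)][1L], " in key '", key,
         "': write rationals as strings, e.g. \"1/2\"", call. = FALSE)
  }
  invisible(NULL)
}

#' Parse and validate a run configuration
#'
#' Reads a JSON configuration for one of the seven commands, applies the
#' command's schema, and rejects anything malformed: unknown keys (named),
#' missing required keys, unquoted float literals (rationals must be
#' `"p/q"` strings), and a zero rate where one is supplied.
#'
#' @param path path to a JSON file.
#' @param command one of `"kink"`, `"pair-check"`, `"construct"`,
#'   `"invert"`, `"verify"`, `"fixture"`, `"simulate"`.
#' @return the validated configuration list, with class `lv_config` and
#'   attribute `command`.
#' @export
parse_config <- function(path, command) {
  command <- match.arg(command, names(config_schema))
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("config must be a JSON object", call. = FALSE)
  }
  schema <- config_schema[[command]]
  unknown <- setdiff(names(cfg), c(schema$required, schema$optional))
  if (length(unknown) > 0L) {
    stop("unknown config key(s) for '", command, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(schema$required, names(cfg))
  if (length(missing) > 0L) {
    stop("missing required config key(s) for '", command, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_rationals(cfg)
  if (!is.null(cfg$eta) && bq_is_zero(bigq(unlist(cfg$eta)))) {
    stop("eta must be nonzero", call. = FALSE)
  }
  structure(cfg, class = "lv_config", command = command)
}

#' Write a trajectory to CSV
#'
#' @param traj a data frame with columns `t`, `x1`, `y1`, `x2`, `y2` (as
#'   returned by [evaluate_solution()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj[, c("t", "x1", "y1", "x2", "y2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
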