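# Run configuration: YAML schema, validation, forcing-expression parsing.

config_schema <- list(
  poroelastic = c("lambda_e", "mu_e", "k"),
  geometry = c("c", "a", "b", "faces"),
  mesh = c("kind", "n", "nx", "ny", "nz", "type"),
  circuit = c("Rbar", "R1", "C", "C1", "L1", "pbar", "A", "U", "y0"),
  coupling = c("variant", "R", "C"),
  time = c("dt", "t_end"),
  forcing = c("g", "psi", "F", "S"),
  output = c("dir", "stride"),
  preset = c("name", "scale", "variant")
)

#' Parse a restricted arithmetic forcing expression
#'
#' Accepts expressions of the spatial coordinates `x`, `y`, `z` and time
#' `t` built from `+ - * / ^ ( )`, the functions `sin`, `cos`, `tan`,
#' `exp`, `sqrt`, `abs`, `log`, and numeric constants (including `pi`).
#' Anything else is rejected, so configuration files cannot execute
#' arbitrary code.
#'
#' @param text expression string, e.g. `"0.1*sin(0.4*pi*t)"`.
#' @return A function `f(x, t)` where `x` is an `n x dim` coordinate matrix
#'   and `t` a scalar time; returns a length-n vector.
#' @export
parse_forcing_expr <- function(text) {
  allowed_fun <- c("+", "-", "*", "/", "^", "(", "sin", "cos", "tan",
                   "exp", "sqrt", "abs", "log")
  allowed_sym <- c("x", "y", "z", "t", "pi")
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop("cannot parse forcing expression: ", text)
  })
  walk <- function(e) {
    if (is.numeric(e) || is.integer(e)) return(invisible())
    if (is.name(e)) {
      if (!as.character(e) %in% allowed_sym) {
        stop("symbol '", as.character(e), "' not allowed in forcing expression")
      }
      return(invisible())
    }
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!fn %in% allowed_fun) {
        stop("function '", fn, "' not allowed in forcing expression")
      }
      for (i in seq_along(e)[-1]) walk(e[[i]])
      return(invisible())
    }
    stop("disallowed construct in forcing expression")
  }
  walk(expr)
  function(x, t) {
    x <- as.matrix(x)
    env <- list2env(list(
      x = x[, 1],
      y = if (ncol(x) >= 2) x[, 2] else rep(0, nrow(x)),
      z = if (ncol(x) >= 3) x[, 3] else rep(0, nrow(x)),
      t = t, pi = base::pi
    ), parent = baseenv())
    v <- eval(expr, env)
    rep_len(as.numeric(v), nrow(x))
  }
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a mapping")
  bad <- setdiff(names(cfg), names(config_schema))
  if (length(bad)) stop("unknown configuration block(s): ",
                        paste(bad, collapse = ", "))
  for (blk in names(cfg)) {
    if (!is.list(cfg[[blk]]) && !is.null(cfg[[blk]])) {
      stop("configuration block '", blk, "' must be a mapping")
    }
    bad <- setdiff(names(cfg[[blk]]), config_schema[[blk]])
    if (length(bad)) {
      stop("unknown key(s) in '", blk, "': ",
           paste(paste0(blk, ".", bad), collapse = ", "))
    }
  }
  chk_pos <- function(blk, key) {
    v <- cfg[[blk]][[key]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      stop("'", blk, ".", key, "' must be positive")
    }
  }
  chk_pos("poroelastic", "k")
  chk_pos("poroelastic", "mu_e")
  v <- cfg$poroelastic$lambda_e
  if (!is.null(v) && (!is.numeric(v) || v < 0)) {
    stop("'poroelastic.lambda_e' must be nonnegative")
  }
  for (key in c("Rbar", "R1", "C", "C1", "L1")) chk_pos("circuit", key)
  for (key in c("R", "C")) chk_pos("coupling", key)
  for (key in c("dt", "t_end")) chk_pos("time", key)
  for (key in c("c", "a", "b")) chk_pos("geometry", key)
  if (!is.null(cfg$coupling$variant) &&
        !tolower(cfg$coupling$variant) %in% c("ppc", "ipc")) {
    stop("'coupling.variant' must be 'ppc' or 'ipc'")
  }
  cfg
}

config_defaults <- list(
  poroelastic = list(lambda_e = 0.5, mu_e = 0.25, k = 1),
  geometry = list(c = 0.5, a = 0.1, b = 0.1, faces = list()),
  mesh = list(kind = "box", n = c(8, 4, 4), type = "hex", nx = 50),
  circuit = list(Rbar = 1, R1 = 1, C = 0.1, C1 = 0.1, L1 = 1, pbar = "0"),
  coupling = list(variant = "ipc", R = 1, C = 0.1),
  time = list(dt = 0.02, t_end = 10),
  forcing = list(),
  output = list(dir = "out", stride = 50)
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown blocks/keys (reporting the
#' offending field path), validates positivity of physical parameters, and
#' fills defaults (time step 0.02 s, final time 10 s, the reference
#' material and circuit values).
#'
#' @param path path to a YAML file.
#' @return A validated configuration list of class `porocirc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg <- validate_config(cfg)
  merged <- config_defaults
  for (blk in names(cfg)) {
    merged[[blk]] <- utils::modifyList(merged[[blk]] %||% list(),
                                       cfg[[blk]] %||% list())
  }
  structure(merged, class = "porocirc_config")
}

#' Save a configuration to YAML
#' @param cfg a configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build a simulation-ready problem from a configuration
#'
#' Instantiates geometry, mesh (3D box or 1D column), material, circuit,
#' coupling and forcing from a validated configuration.
#'
#' @param cfg a configuration from [load_config()] (or a compatible list).
#' @return List with `problem` (a [biot0d_problem()]), `dt`, `t_end`,
#'   `output`.
#' @export
build_problem <- function(cfg) {
  if (!inherits(cfg, "porocirc_config")) cfg <- validate_config(cfg)
  merged <- config_defaults
  for (blk in names(cfg)) {
    merged[[blk]] <- utils::modifyList(merged[[blk]] %||% list(),
                                       cfg[[blk]] %||% list())
  }
  cfg <- merged
  params <- poro_params(cfg$poroelastic$lambda_e, cfg$poroelastic$mu_e,
                        cfg$poroelastic$k)
  geom <- geometry_box(cfg$geometry$c, cfg$geometry$a, cfg$geometry$b,
                       faces = cfg$geometry$faces %||% list())
  mesh <- if (identical(cfg$mesh$kind, "column")) {
    mesh_interval(geom, cfg$mesh$nx %||% 50)
  } else {
    mesh_box(geom, unlist(cfg$mesh$n), cfg$mesh$type %||% "hex")
  }
  fr <- cfg$forcing
  to_fn <- function(key) if (!is.null(fr[[key]])) parse_forcing_expr(fr[[key]])
  psi_fn <- to_fn("psi")
  S_fn <- to_fn("S")
  vec_fn <- function(key, dim) {
    spec <- fr[[key]]
    if (is.null(spec)) return(NULL)
    if (!is.list(spec)) spec <- list(x = spec)
    comp <- lapply(c("x", "y", "z")[seq_len(dim)], function(cc) {
      if (!is.null(spec[[cc]])) parse_forcing_expr(spec[[cc]])
    })
    function(x, t) {
      out <- matrix(0, nrow(as.matrix(x)), dim)
      for (c_ in seq_len(dim)) {
        if (!is.null(comp[[c_]])) out[, c_] <- comp[[c_]](x, t)
      }
      out
    }
  }
  dim <- if (identical(cfg$mesh$kind, "column")) 1L else 3L
  forcing <- forcing_data(
    F = vec_fn("F", dim), S = S_fn, g = vec_fn("g", dim), psi = psi_fn,
    y0 = if (!is.null(cfg$circuit$y0)) as.numeric(unlist(cfg$circuit$y0))
  )
  disc <- biot_discretization(mesh, params, forcing)
  circ <- if (!is.null(cfg$circuit$A)) {
    Amat <- do.call(rbind, lapply(cfg$circuit$A, as.numeric))
    circuit_model(Amat, as.numeric(unlist(cfg$circuit$U)),
                  C_conn = cfg$coupling$C)
  } else {
    pb <- parse_forcing_expr(cfg$circuit$pbar %||% "0")
    example_circuit(cfg$circuit$Rbar, cfg$circuit$R1, cfg$circuit$C,
                    cfg$circuit$C1, cfg$circuit$L1,
                    pbar = function(t) pb(matrix(0, 1, 1), t))
  }
  cpl <- if (!is.null(disc$sigma)) {
    coupling_spec(cfg$coupling$variant, cfg$coupling$R, cfg$coupling$C,
                  m_sigma = disc$sigma$m_sigma)
  }
  problem <- if (is.null(cpl)) biot0d_problem(disc) else
    biot0d_problem(disc, circ, cpl)
  list(problem = problem, dt = cfg$time$dt, t_end = cfg$time$t_end,
       output = cfg$output)
}
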