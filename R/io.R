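#' Write a rod configuration in extended-XYZ format
#'
#' One record per rod with position and orientation columns
#' (\code{Properties=pos:R:3:orient:R:3}); the comment line carries the
#' box as a \code{Lattice="..."} entry for periodic configurations. All
#' values are written with 12 significant digits so a round trip is
#' faithful.
#'
#' @param config a [rod_configuration()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(config, path) {
  stopifnot(inherits(config, "rod_config"))
  n <- nrow(config$positions)
  hdr <- 'Properties=pos:R:3:orient:R:3'
  if (config$periodic) {
    L <- config$box
    hdr <- sprintf('Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" %s pbc="T T T"',
                   L[1], L[2], L[3], hdr)
  }
  lines <- c(as.character(n), hdr)
  if (n > 0) {
    m <- cbind(config$positions, config$orientations)
    lines <- c(lines, apply(m, 1, function(r)
      paste(sprintf("%.12g", r), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a rod configuration from extended-XYZ
#'
#' @param path file written by [write_xyz()] (or compatible: six numeric
#'   columns per rod, position then orientation).
#' @return A [rod_configuration()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("not an extended-XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) stop("bad rod count in ", path)
  hdr <- lines[2]
  if (!grepl("orient", hdr, fixed = TRUE))
    stop("missing orientation columns in extended-XYZ header")
  box <- NULL
  lm <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
  if (length(lm) == 1) {
    v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lm),
                             "[[:space:]]+")[[1]])
    if (length(v) != 9) stop("malformed Lattice entry")
    box <- v[c(1, 5, 9)]
  }
  if (n == 0)
    return(rod_configuration(matrix(numeric(0), 0, 3),
                             matrix(numeric(0), 0, 3), box = box,
                             periodic = !is.null(box)))
  body <- lines[3:(2 + n)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                             as.numeric))
  if (ncol(m) < 6) stop("expected 6 columns (pos, orient) per rod")
  ori <- m[, 4:6, drop = FALSE]
  nrm <- sqrt(rowSums(ori^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("orientation columns are not unit vectors")
  ori <- ori / nrm
  rod_configuration(m[, 1:3, drop = FALSE], ori, box = box,
                    periodic = !is.null(box))
}

# the full default configuration tree; also the validation schema
.default_config <- function() {
  list(
    command = "optimize-lattice",
    seed = 1L,
    potential = list(kappa_star = 20, M = 15L, Z = 1, lambda_ref = 1,
                     n_trunc = 10L),
    lattice = list(stacking = "ABC", rho_star = 10, l_xy_star = 1 / 3,
                   phi = 0, theta1 = 0, theta2 = 0),
    scan = list(l_xy_min = 0, l_xy_max = 0, n_grid = 60L,
                phi_step = 2.5),   # 0 = automatic bracket
    mc = list(temperature = 0, n_steps = 1000L, box_moves = TRUE,
              box_every = 10L, delta_translate = 0.02, delta_rotate = 0.1,
              sample_every = 10L),
    supercell = list(n_x = 2L, n_y = 4L, n_z = 12L),
    cnc = list(a_nm = 150, d_nm = 7, xi = 2, l_B_nm = 0.71,
               rho_star_min = 1, rho_star_max = 30),
    output = list(path = "")
  )
}

.check_keys <- function(value, template, where) {
  extra <- setdiff(names(value), names(template))
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s", " in ", where,
         ": ", paste(extra, collapse = ", "), call. = FALSE)
  for (nm in names(value))
    if (is.list(template[[nm]]))
      .check_keys(value[[nm]], template[[nm]], paste0(where, "$", nm))
  invisible(TRUE)
}

#' Read a run configuration
#'
#' JSON configuration with explicit defaults for every module; keys not in
#' the schema are rejected, partial files are completed with the
#' defaults, and basic physical validity (positive \eqn{\kappa^*},
#' density, step counts) is enforced.
#'
#' @param path JSON file, or \code{NULL} for the full default config.
#' @return A named list of class \code{"run_config"}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    .check_keys(user, cfg, "config")
    for (nm in names(user)) {
      if (is.list(cfg[[nm]])) cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      else cfg[[nm]] <- user[[nm]]
    }
  }
  with(cfg$potential, {
    if (kappa_star <= 0) stop("kappa_star must be positive")
    if (M < 1) stop("M must be >= 1")
  })
  if (cfg$lattice$rho_star <= 0) stop("rho_star must be positive")
  if (cfg$mc$temperature < 0) stop("temperature must be >= 0")
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration
#'
#' Serialises the configuration to pretty-printed JSON; reading it back
#' re-serialises byte-identically.
#'
#' @param cfg a \code{"run_config"} list.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
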