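# Vessel network representation: one row per endothelial segment (one lattice
# voxel), with a parent link forming a forest rooted at the pre-existing
# vasculature. Columns:
#   id, parent_id (-1 for roots), x, y, z (1-based lattice indices),
#   age (iterations), radius (m), tip (logical), acc (accumulated tip growth,
#   grid steps), stall (consecutive stalled iterations).

empty_vessel_network <- function() {
  data.frame(id = integer(), parent_id = integer(),
             x = integer(), y = integer(), z = integer(),
             age = numeric(), radius = numeric(), tip = logical(),
             acc = numeric(), stall = integer())
}

new_segments <- function(id, parent_id, x, y, z, age, radius, tip,
                         acc = 0, stall = 0L) {
  data.frame(id = as.integer(id), parent_id = as.integer(parent_id),
             x = as.integer(x), y = as.integer(y), z = as.integer(z),
             age = as.numeric(age), radius = as.numeric(radius),
             tip = as.logical(tip), acc = as.numeric(acc),
             stall = as.integer(stall))
}

vessel_occupancy <- function(vessels, dims) {
  occ <- array(FALSE, dims)
  if (nrow(vessels)) occ[cbind(vessels$x, vessels$y, vessels$z)] <- TRUE
  occ
}

validate_vessel_network <- function(v) {
  if (anyDuplicated(v$id)) stop("duplicate vessel segment ids", call. = FALSE)
  nonroot <- v$parent_id != -1L
  if (any(nonroot & !(v$parent_id %in% v$id)))
    stop("vessel segment references an unknown parent", call. = FALSE)
  invisible(v)
}

#' Vessel radius from endothelial age
#'
#' Saturating maturation map: `R(age) = R_max * k_AR1 * age / (k_AR2 + age)`,
#' monotone non-decreasing in age and bounded by `R_max * k_AR1`.
#'
#' @param age vector of segment ages (iterations).
#' @param cfg a [sim_config()].
#' @return radii in metres.
#' @export
vessel_radius <- function(age, cfg) {
  cfg$R_max * cfg$k_AR1 * pmax(age, 0) / (cfg$k_AR2 + pmax(age, 0))
}

#' Age and mature a vessel network
#'
#' Perfused segments age by one iteration per call and their radii follow the
#' saturating maturation map [vessel_radius()]. Tips that have been stalled
#' for at least `stall_steps` consecutive iterations are treated as
#' unperfused and age backwards instead, which is the route to age-zero
#' pruning.
#'
#' @param vessels a vessel network data frame.
#' @param cfg a [sim_config()].
#' @return the updated network.
#' @export
age_and_radius_update <- function(vessels, cfg) {
  if (!nrow(vessels)) return(vessels)
  regress <- vessels$tip & vessels$stall >= cfg$stall_steps
  vessels$age <- vessels$age + ifelse(regress, -1, 1)
  vessels$radius <- vessel_radius(vessels$age, cfg)
  vessels
}

#' Prune dead vessel segments
#'
#' Removes every segment whose age has reached zero (or below), together with
#' its entire downstream subtree, and leaves the parent/child structure of
#' the survivors intact.
#'
#' @param vessels a vessel network data frame.
#' @return the pruned network.
#' @export
prune_vessels <- function(vessels) {
  if (!nrow(vessels)) return(vessels)
  dead <- vessels$age <= 0
  if (!any(dead)) return(vessels)
  # propagate death downstream until fixed point
  repeat {
    orphan <- vessels$parent_id %in% vessels$id[dead] & !dead
    if (!any(orphan)) break
    dead <- dead | orphan
  }
  vessels[!dead, , drop = FALSE]
}

#' Generate a parent-vasculature fixture
#'
#' Deterministic pre-existing vasculature for sprouting to initiate from.
#' `single_axis` is one straight vessel spanning the domain parallel to the
#' x axis, laterally offset from the tumor centre by
#' `parent_offset_frac * grid_n` in y and centred in z. `face_grid` is a comb
#' of `parent_n_vessels` parallel vessels in the `y = offset` plane, evenly
#' spaced in z. Segments start mature (`parent_age` iterations old).
#'
#' @param cfg a [sim_config()].
#' @param style `"single_axis"` or `"face_grid"`.
#' @return a vessel network data frame.
#' @export
generate_parent_vessels <- function(cfg, style = c("single_axis", "face_grid")) {
  style <- match.arg(style)
  n <- cfg$grid_n
  c0 <- as.integer(ceiling(n / 2))
  y0 <- max(2L, c0 - as.integer(round(cfg$parent_offset_frac * n)))
  r0 <- vessel_radius(cfg$parent_age, cfg)
  if (style == "single_axis") {
    xs <- seq_len(n)
    return(new_segments(
      id = xs, parent_id = c(-1L, xs[-n]),
      x = xs, y = rep(y0, n), z = rep(c0, n),
      age = cfg$parent_age, radius = r0, tip = FALSE))
  }
  nv <- cfg$parent_n_vessels
  zs <- as.integer(round(seq(2L, n - 1L, length.out = nv)))
  segs <- lapply(seq_len(nv), function(v) {
    xs <- seq_len(n)
    ids <- (v - 1L) * n + xs
    new_segments(id = ids, parent_id = c(-1L, ids[-n]),
                 x = xs, y = rep(y0, n), z = rep(zs[v], n),
                 age = cfg$parent_age, radius = r0, tip = FALSE)
  })
  do.call(rbind, segs)
}

#' Vessel network file I/O
#'
#' Networks are exchanged as a comma-separated edge list with the header
#' `id,parent_id,x,y,z,radius,age` and a leading comment line declaring the
#' coordinate units (`# units: grid` for 1-based lattice indices or
#' `# units: m` for metres, converted on load using the configured spacing).
#' Root segments carry `parent_id = -1`. Malformed rows, duplicate ids and
#' references to unknown parents are errors naming the offending line.
#'
#' @param path file path.
#' @param vessels a vessel network data frame.
#' @param cfg a [sim_config()] (needed to convert metre coordinates).
#' @param units `"grid"` or `"m"` for writing.
#' @return `load_vessel_file()` returns a vessel network; `write_vessel_file()`
#'   its path, invisibly.
#' @export
load_vessel_file <- function(path, cfg = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty vessel file: ", path, call. = FALSE)
  units <- "grid"
  skip <- 0L
  if (grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("units:\\s*(\\S+)", lines[1]))[[1]]
    if (length(m) == 2) units <- m[2]
    skip <- 1L
  }
  if (!units %in% c("grid", "m"))
    stop("vessel file line 1: unknown units '", units, "'", call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, skip = skip, header = TRUE, strip.white = TRUE),
    error = function(e) stop("malformed vessel file: ", conditionMessage(e),
                             call. = FALSE))
  need <- c("id", "parent_id", "x", "y", "z", "radius", "age")
  if (!all(need %in% names(tab)))
    stop("vessel file header must contain: ", paste(need, collapse = ","),
         call. = FALSE)
  header_lines <- skip + 1L
  bad <- which(!stats::complete.cases(tab[need]))
  if (length(bad))
    stop("vessel file line ", bad[1] + header_lines, ": malformed row",
         call. = FALSE)
  if (units == "m") {
    if (is.null(cfg)) stop("a config is required to load metre coordinates",
                           call. = FALSE)
    for (cc in c("x", "y", "z")) tab[[cc]] <- round(tab[[cc]] / cfg$spacing_m) + 1L
  }
  dup <- which(duplicated(tab$id))
  if (length(dup))
    stop("vessel file line ", dup[1] + header_lines, ": duplicate id ",
         tab$id[dup[1]], call. = FALSE)
  orphan <- which(tab$parent_id != -1 & !(tab$parent_id %in% tab$id))
  if (length(orphan))
    stop("vessel file line ", orphan[1] + header_lines,
         ": unknown parent id ", tab$parent_id[orphan[1]], call. = FALSE)
  v <- new_segments(tab$id, tab$parent_id, tab$x, tab$y, tab$z,
                    tab$age, tab$radius, tip = FALSE)
  # leaves are growing tips
  v$tip <- !(v$id %in% v$parent_id)
  validate_vessel_network(v)
}

#' @rdname load_vessel_file
#' @export
write_vessel_file <- function(vessels, path, cfg = NULL, units = c("grid", "m")) {
  units <- match.arg(units)
  out <- vessels[, c("id", "parent_id", "x", "y", "z", "radius", "age")]
  if (units == "m") {
    if (is.null(cfg)) stop("a config is required to write metre coordinates",
                           call. = FALSE)
    for (cc in c("x", "y", "z")) out[[cc]] <- (out[[cc]] - 1L) * cfg$spacing_m
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
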