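#' Synthetic membrane-like particle configurations
#'
#' Generates a geometric stand-in for a lipid bilayer patch: head
#' particles (alternating phosphate-like `head_P` and amine-like
#' `head_N`) jittered on the two leaflet planes at
#' `z = midplane +/- leaflet_sep / 2`, tail carbons between the leaflets,
#' bulk water outside, and optionally a planted cylindrical water pore
#' spanning the membrane. The planted pore places waters at bulk density
#' (`v_w = 0.030` nm^3 per water) inside a cylinder of the requested
#' radius and pulls nearby headgroups toward the midplane, emulating a
#' toroidal pore rim. The configuration is geometry only - no energetics.
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param leaflet_sep distance between head planes (nm); the default 2.6
#'   echoes the `|z| = 1.3` nm flip-flop state boundaries.
#' @param box periodic box lengths `c(Lx, Ly, Lz)` (nm).
#' @param pore_radius planted pore radius (nm); 0 = intact membrane.
#' @param n_pore_waters override the bulk-density water count of the
#'   planted pore.
#' @param seed integer seed.
#' @param tails_per_lipid tail beads per lipid.
#' @return A `membrane_config`: tibble with columns `x`, `y`, `z`,
#'   `type`, plus attributes `box`, `midplane_z` and `planted` (pore
#'   metadata).
#' @examples
#' cfg <- generate_membrane_config(64, pore_radius = 0.4, seed = 1)
#' attr(cfg, "planted")
#' @export
generate_membrane_config <- function(n_lipids_per_leaflet = 100,
                                     leaflet_sep = 2.6,
                                     box = c(6, 6, 6),
                                     pore_radius = 0,
                                     n_pore_waters = NULL,
                                     seed = NULL,
                                     tails_per_lipid = 2) {
  stopifnot(pore_radius >= 0, leaflet_sep > 0, length(box) == 3)
  if (pore_radius > min(box[1:2]) / 2) {
    stop("`pore_radius` exceeds half the lateral box.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mid <- box[3] / 2
  v_w <- 0.030
  half <- leaflet_sep / 2
  n_side <- ceiling(sqrt(n_lipids_per_leaflet))
  grid <- expand.grid(ix = seq_len(n_side) - 0.5, iy = seq_len(n_side) - 0.5)
  grid <- grid[seq_len(n_lipids_per_leaflet), ]
  one_leaflet <- function(zplane) {
    tibble::tibble(
      x = grid$ix / n_side * box[1] + rnorm(n_lipids_per_leaflet, sd = 0.08),
      y = grid$iy / n_side * box[2] + rnorm(n_lipids_per_leaflet, sd = 0.08),
      z = zplane + rnorm(n_lipids_per_leaflet, sd = 0.08),
      type = rep_len(c("head_P", "head_N"), n_lipids_per_leaflet)
    )
  }
  heads <- dplyr::bind_rows(one_leaflet(mid + half), one_leaflet(mid - half))
  n_tail <- 2 * n_lipids_per_leaflet * tails_per_lipid
  tails <- tibble::tibble(
    x = runif(n_tail, 0, box[1]),
    y = runif(n_tail, 0, box[2]),
    z = mid + runif(n_tail, -(half - 0.25), half - 0.25),
    type = "tail_C"
  )
  water_margin <- 0.2
  slab_lo <- c(0, mid + half + water_margin)
  slab_hi <- c(mid - half - water_margin, box[3])
  n_bulk <- round(box[1] * box[2] * (slab_hi - slab_lo) / v_w * 0.15)
  bulk <- dplyr::bind_rows(lapply(1:2, function(i) {
    tibble::tibble(
      x = runif(n_bulk[i], 0, box[1]),
      y = runif(n_bulk[i], 0, box[2]),
      z = runif(n_bulk[i], slab_lo[i], slab_hi[i]),
      type = "water_O"
    )
  }))
  planted <- list(pore_radius = pore_radius, center = box[1:2] / 2,
                  n_pore_waters = 0L, seed = seed)
  pore <- NULL
  if (pore_radius > 0) {
    nw <- if (is.null(n_pore_waters)) {
      round(pi * pore_radius^2 * leaflet_sep / v_w)
    } else n_pore_waters
    r <- pore_radius * sqrt(runif(nw))
    th <- runif(nw, 0, 2 * pi)
    pore <- tibble::tibble(
      x = planted$center[1] + r * cos(th),
      y = planted$center[2] + r * sin(th),
      z = mid + runif(nw, -half, half),
      type = "water_O"
    )
    planted$n_pore_waters <- nw
    # pull headgroups near the pore axis toward the midplane (toroidal rim)
    d <- sqrt((heads$x - planted$center[1])^2 + (heads$y - planted$center[2])^2)
    rim <- d < 1.6 * pore_radius
    shrink <- (d[rim] / (1.6 * pore_radius))^0.7
    heads$z[rim] <- mid + (heads$z[rim] - mid) * shrink
  }
  cfg <- dplyr::bind_rows(heads, tails, bulk, pore)
  cfg$x <- cfg$x %% box[1]
  cfg$y <- cfg$y %% box[2]
  cfg$z <- cfg$z %% box[3]
  new_membrane_config(cfg, box = box, midplane_z = mid, planted = planted)
}

new_membrane_config <- function(df, box, midplane_z, planted = NULL) {
  stopifnot(all(c("x", "y", "z", "type") %in% names(df)))
  structure(tibble::as_tibble(df),
            box = box, midplane_z = midplane_z, planted = planted,
            class = c("membrane_config", class(tibble::tibble())))
}

#' Assemble a membrane configuration from particle coordinates
#'
#' @param df data frame with columns `x`, `y`, `z`, `type` (types among
#'   `head_P`, `head_N`, `water_O`, `tail_C`).
#' @param box periodic box lengths (nm).
#' @param midplane_z membrane midplane (nm); default `box[3] / 2`.
#' @export
membrane_config <- function(df, box, midplane_z = box[3] / 2) {
  df$x <- df$x %% box[1]
  df$y <- df$y %% box[2]
  df$z <- df$z %% box[3]
  new_membrane_config(df, box = box, midplane_z = midplane_z)
}

#' Read/write membrane configurations as CSV
#'
#' Plain CSV with columns `x,y,z,type`; the box and midplane ride along
#' in `#`-prefixed header comments so the file round-trips losslessly.
#'
#' @param cfg a `membrane_config`.
#' @param path file path.
#' @export
write_membrane_csv <- function(cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# box=", paste(attr(cfg, "box"), collapse = ",")),
    paste0("# midplane_z=", attr(cfg, "midplane_z"))
  ), con)
  write.csv(as.data.frame(cfg)[, c("x", "y", "z", "type")], con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_membrane_csv
#' @export
read_membrane_csv <- function(path) {
  hdr <- readLines(path, n = 5)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    line <- hdr[grepl(paste0("^# ", key, "="), hdr)]
    as.numeric(strsplit(sub(paste0("^# ", key, "="), "", line), ",")[[1]])
  }
  df <- read.csv(path, comment.char = "#")
  new_membrane_config(df, box = get_field("box"),
                      midplane_z = get_field("midplane_z"))
}
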