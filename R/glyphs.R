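#' Dumb-bell glyphs from tensor decompositions
#'
#' Turns the principal components of decomposed shielding tensors into
#' oriented dumb-bell glyphs, the visual grammar of tensor plots: one rod
#' with two end lobes per principal axis, centred on the probe, with length
#' and lobe size proportional to `|t|` and colour by the sign of the NICS
#' contribution `-t` (blue = shielded/aromatic for negative NICS, red =
#' deshielded/antiaromatic for positive). Components below the display
#' threshold are omitted; lengths are capped at `max_length`. A tensor whose
#' right-eigen decomposition produced a complex pair keeps its
#' `complex_flag`, and such glyphs are rendered semi-transparent — visually
#' distinct, never hidden.
#'
#' @param decomposition a tibble from [vist_decompose()].
#' @param scale glyph length per ppm, Angstrom/ppm.
#' @param threshold display threshold, ppm; components with `|t|` below it
#'   are dropped.
#' @param max_length length cap, Angstrom.
#' @param lobe_ratio lobe radius as a fraction of the half-length.
#' @return a glyph tibble: `label`, `component`, origin `x`, `y`, `z`, unit
#'   `axis_x/y/z`, `t`, `nics`, `length`, `lobe_radius`, `colour`
#'   (`"shielded-blue"` or `"deshielded-red"`), `complex_flag`.
#' @examples
#' shielding_tensor(diag(c(13.3, 6.7, 6.7)), label = "NICS(0)") |>
#'   vist_decompose() |>
#'   build_glyphs()
#' @export
build_glyphs <- function(decomposition, scale = 0.04, threshold = 1,
                         max_length = 3, lobe_ratio = 0.25) {
  stopifnot(all(c("label", "component", "t", "nics") %in% names(decomposition)))
  if (!is_number(scale) || scale <= 0) {
    stop("`scale` must be a positive number (Angstrom/ppm)", call. = FALSE)
  }
  if (!is_number(threshold) || threshold < 0) {
    stop("`threshold` must be >= 0 (ppm)", call. = FALSE)
  }
  g <- dplyr::filter(decomposition, abs(.data$t) >= threshold)
  len <- pmin(scale * abs(g$t), max_length)
  dplyr::transmute(
    g,
    label = .data$label,
    component = .data$component,
    x = .data$x, y = .data$y, z = .data$z,
    axis_x = .data$axis_x, axis_y = .data$axis_y, axis_z = .data$axis_z,
    t = .data$t,
    nics = .data$nics,
    length = len,
    lobe_radius = lobe_ratio * len / 2,
    colour = ifelse(.data$nics < 0, "shielded-blue", "deshielded-red"),
    complex_flag = .data$complex_flag
  )
}

#' Assemble a renderable scene
#'
#' A scene bundles a glyph tibble with the molecular structure it annotates
#' plus the scale metadata, ready for [render_tcl()], [export_scene()] or
#' [plot_vist_scene()].
#'
#' @param glyphs a glyph tibble from [build_glyphs()].
#' @param molecule optional molecule tibble drawn alongside the glyphs.
#' @param scale,threshold the mapping metadata recorded with the scene.
#' @return a `"vist_scene"` object.
#' @export
vist_scene <- function(glyphs, molecule = NULL, scale = 0.04, threshold = 1) {
  need <- c("label", "x", "y", "z", "axis_x", "axis_y", "axis_z",
            "nics", "length", "lobe_radius", "colour", "complex_flag")
  if (!all(need %in% names(glyphs))) {
    stop("`glyphs` is not a glyph tibble; see build_glyphs()", call. = FALSE)
  }
  if (!is.null(molecule)) molecule <- as_molecule(molecule)
  structure(
    list(
      molecule = molecule,
      glyphs = tibble::as_tibble(glyphs),
      scale = scale,
      threshold = threshold
    ),
    class = "vist_scene"
  )
}

#' @export
print.vist_scene <- function(x, ...) {
  cat(sprintf(
    "<vist_scene> %d glyph(s)%s; scale %g A/ppm, threshold %g ppm\n",
    nrow(x$glyphs),
    if (is.null(x$molecule)) "" else sprintf(", %d atom(s)", nrow(x$molecule)),
    x$scale, x$threshold
  ))
  invisible(x)
}

glyph_ends <- function(g) {
  half <- g$length / 2
  ax <- c(g$axis_x, g$axis_y, g$axis_z)
  o <- c(g$x, g$y, g$z)
  list(a = o - half * ax, b = o + half * ax, axis = ax, origin = o)
}

#' Render a scene as a VMD draw script
#'
#' Emits a self-contained TCL script in the VMD draw-command dialect:
#' colours and materials are defined at the top, then each glyph becomes one
#' cylinder plus two end-lobe spheres. Shielded (negative NICS) glyphs are
#' blue, deshielded red; complex-flagged glyphs use a transparent material.
#' Output is byte-deterministic (fixed 6-decimal coordinates, LF endings).
#'
#' @param scene a [vist_scene()].
#' @return a single string with the TCL script.
#' @export
render_tcl <- function(scene) {
  stopifnot(inherits(scene, "vist_scene"))
  out <- c(
    "# vistr shielding-tensor scene (VMD draw dialect)",
    sprintf(
      "# scale %s A/ppm, threshold %s ppm, %d glyph(s)",
      num6(scene$scale), num6(scene$threshold), nrow(scene$glyphs)
    ),
    "material add VistSolid copy Opaque",
    "material add VistGhost copy Transparent",
    "color change rgb 30 0.200000 0.300000 0.800000",
    "color change rgb 31 0.800000 0.200000 0.200000"
  )
  fmt_pt <- function(p) sprintf("{%s %s %s}", num6(p[1]), num6(p[2]), num6(p[3]))
  for (i in seq_len(nrow(scene$glyphs))) {
    g <- scene$glyphs[i, ]
    e <- glyph_ends(g)
    out <- c(
      out,
      sprintf("# glyph %s component %d (NICS %s ppm)", g$label, g$component, num6(g$nics)),
      sprintf(
        "draw material %s",
        if (isTRUE(g$complex_flag)) "VistGhost" else "VistSolid"
      ),
      sprintf("draw color %d", if (g$colour == "shielded-blue") 30L else 31L),
      sprintf(
        "draw cylinder %s %s radius %s resolution 24 filled yes",
        fmt_pt(e$a), fmt_pt(e$b), num6(0.4 * g$lobe_radius)
      ),
      sprintf("draw sphere %s radius %s resolution 24", fmt_pt(e$a), num6(g$lobe_radius)),
      sprintf("draw sphere %s radius %s resolution 24", fmt_pt(e$b), num6(g$lobe_radius))
    )
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Export a scene as JSON or OBJ
#'
#' JSON is a lossless record of the scene (molecule, glyph table, scale
#' metadata) that [scene_from_json()] reads back; OBJ is a triangulated mesh
#' with one group per glyph — a cylinder shell (no caps; the end lobes cover
#' the ends) plus two UV spheres. Both are UTF-8 with LF endings and fixed
#' 6-decimal coordinates (OBJ), so output is byte-deterministic.
#'
#' @param scene a [vist_scene()].
#' @param format `"json"` or `"obj"`.
#' @param n_ring cylinder/meridian resolution (OBJ).
#' @param n_lat sphere latitude rings excluding poles (OBJ); each sphere has
#'   `n_lat * n_ring + 2` vertices.
#' @return a single string.
#' @export
export_scene <- function(scene, format = c("json", "obj"),
                         n_ring = 16L, n_lat = 8L) {
  format <- match.arg(format)
  if (format == "json") scene_to_json(scene) else scene_to_obj(scene, n_ring, n_lat)
}

#' @rdname export_scene
#' @export
scene_to_json <- function(scene) {
  stopifnot(inherits(scene, "vist_scene"))
  jsonlite::toJSON(
    list(
      format = "vistr-scene",
      version = 1L,
      scale = scene$scale,
      threshold = scene$threshold,
      molecule = scene$molecule,
      glyphs = scene$glyphs
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
}

#' @rdname export_scene
#' @param text JSON text or a path to a JSON file.
#' @export
scene_from_json <- function(text) {
  obj <- jsonlite::fromJSON(if (length(text) == 1L && !grepl("[{]", text)) text else paste(text, collapse = "\n"))
  if (!identical(obj$format, "vistr-scene")) {
    stop("not a vistr scene JSON record", call. = FALSE)
  }
  mol <- if (is.null(obj$molecule)) NULL else as_molecule(tibble::as_tibble(obj$molecule))
  glyphs <- tibble::as_tibble(obj$glyphs)
  if (nrow(glyphs) == 0L) {
    glyphs <- empty_glyph_table()
  } else {
    # JSON has no int/double distinction; restore the glyph column types
    for (cn in c("x", "y", "z", "axis_x", "axis_y", "axis_z", "t", "nics",
                 "length", "lobe_radius")) {
      glyphs[[cn]] <- as.numeric(glyphs[[cn]])
    }
    glyphs$component <- as.integer(glyphs$component)
    glyphs$complex_flag <- as.logical(glyphs$complex_flag)
  }
  vist_scene(glyphs,
    molecule = mol,
    scale = obj$scale, threshold = obj$threshold
  )
}

empty_glyph_table <- function() {
  tibble::tibble(
    label = character(), component = integer(),
    x = numeric(), y = numeric(), z = numeric(),
    axis_x = numeric(), axis_y = numeric(), axis_z = numeric(),
    t = numeric(), nics = numeric(), length = numeric(),
    lobe_radius = numeric(), colour = character(), complex_flag = logical()
  )
}

#' @rdname export_scene
#' @export
scene_to_obj <- function(scene, n_ring = 16L, n_lat = 8L) {
  stopifnot(inherits(scene, "vist_scene"), n_ring >= 3L, n_lat >= 1L)
  out <- c(
    "# vistr shielding-tensor scene (OBJ mesh)",
    sprintf("# %d glyph(s), n_ring=%d, n_lat=%d", nrow(scene$glyphs), n_ring, n_lat)
  )
  voffset <- 0L
  for (i in seq_len(nrow(scene$glyphs))) {
    g <- scene$glyphs[i, ]
    e <- glyph_ends(g)
    basis <- plane_basis(e$axis)
    mesh_v <- NULL
    mesh_f <- NULL
    add <- function(v, f) {
      mesh_f <<- rbind(mesh_f, f + nrow(mesh_v %||% matrix(0, 0, 3)))
      mesh_v <<- rbind(mesh_v, v)
    }
    # cylinder shell
    phi <- (seq_len(n_ring) - 1L) * 2 * pi / n_ring
    ring <- outer(cos(phi), basis$e1) + outer(sin(phi), basis$e2)
    rad <- 0.4 * g$lobe_radius
    va <- sweep(rad * ring, 2, e$a, `+`)
    vb <- sweep(rad * ring, 2, e$b, `+`)
    cf <- NULL
    for (k in seq_len(n_ring)) {
      k2 <- if (k == n_ring) 1L else k + 1L
      cf <- rbind(
        cf,
        c(k, n_ring + k, n_ring + k2),
        c(k, n_ring + k2, k2)
      )
    }
    add(rbind(va, vb), cf)
    # two end-lobe spheres
    for (cen in list(e$a, e$b)) {
      sph <- uv_sphere(cen, g$lobe_radius, n_ring, n_lat, basis, e$axis)
      add(sph$v, sph$f)
    }
    out <- c(
      out,
      sprintf("g glyph_%s_c%d", gsub("[^A-Za-z0-9_.-]", "_", g$label), g$component),
      sprintf("v %s %s %s", num6(mesh_v[, 1]), num6(mesh_v[, 2]), num6(mesh_v[, 3])),
      sprintf(
        "f %d %d %d",
        mesh_f[, 1] + voffset, mesh_f[, 2] + voffset, mesh_f[, 3] + voffset
      )
    )
    voffset <- voffset + nrow(mesh_v)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# UV sphere: n_lat latitude rings (poles excluded) x n_ring meridians + 2 poles
uv_sphere <- function(centre, radius, n_ring, n_lat, basis, axis) {
  theta <- seq_len(n_lat) * pi / (n_lat + 1L)
  phi <- (seq_len(n_ring) - 1L) * 2 * pi / n_ring
  v <- matrix(0, n_lat * n_ring + 2L, 3L)
  v[1L, ] <- centre + radius * axis # north pole
  row <- 1L
  for (it in seq_len(n_lat)) {
    ct <- cos(theta[it])
    st <- sin(theta[it])
    for (ip in seq_len(n_ring)) {
      row <- row + 1L
      v[row, ] <- centre + radius *
        (ct * axis + st * (cos(phi[ip]) * basis$e1 + sin(phi[ip]) * basis$e2))
    }
  }
  v[n_lat * n_ring + 2L, ] <- centre - radius * axis # south pole
  f <- NULL
  idx <- function(it, ip) 1L + (it - 1L) * n_ring + ip
  for (ip in seq_len(n_ring)) {
    ip2 <- if (ip == n_ring) 1L else ip + 1L
    f <- rbind(f, c(1L, idx(1L, ip), idx(1L, ip2)))
  }
  if (n_lat > 1L) {
    for (it in seq_len(n_lat - 1L)) {
      for (ip in seq_len(n_ring)) {
        ip2 <- if (ip == n_ring) 1L else ip + 1L
        f <- rbind(
          f,
          c(idx(it, ip), idx(it + 1L, ip), idx(it + 1L, ip2)),
          c(idx(it, ip), idx(it + 1L, ip2), idx(it, ip2))
        )
      }
    }
  }
  south <- n_lat * n_ring + 2L
  for (ip in seq_len(n_ring)) {
    ip2 <- if (ip == n_ring) 1L else ip + 1L
    f <- rbind(f, c(south, idx(n_lat, ip2), idx(n_lat, ip)))
  }
  list(v = v, f = f)
}

#' Plot a scene as a 2D projection
#'
#' Projects glyph rods and atoms onto a coordinate plane with ggplot2 —
#' a quick-look companion to the full 3D TCL/OBJ exports. Rod length and
#' colour carry the same encoding as the 3D scene.
#'
#' @param scene a [vist_scene()].
#' @param plane `"xz"`, `"xy"` or `"yz"`.
#' @return a ggplot.
#' @export
plot_vist_scene <- function(scene, plane = c("xz", "xy", "yz")) {
  stopifnot(inherits(scene, "vist_scene"))
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  g <- scene$glyphs
  seg <- tibble::tibble(
    h = g[[ax[1]]] - g$length / 2 * g[[paste0("axis_", ax[1])]],
    v = g[[ax[2]]] - g$length / 2 * g[[paste0("axis_", ax[2])]],
    hend = g[[ax[1]]] + g$length / 2 * g[[paste0("axis_", ax[1])]],
    vend = g[[ax[2]]] + g$length / 2 * g[[paste0("axis_", ax[2])]],
    colour = g$colour
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$h, y = .data$v, xend = .data$hend, yend = .data$vend,
        colour = .data$colour
      ),
      linewidth = 1.2, lineend = "round"
    ) +
    ggplot2::scale_colour_manual(
      values = c("shielded-blue" = "#2166ac", "deshielded-red" = "#b2182b"),
      name = NULL
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("%s (Å)", ax[1]), y = sprintf("%s (Å)", ax[2])) +
    ggplot2::theme_minimal()
  if (!is.null(scene$molecule)) {
    m <- scene$molecule
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(h = m[[ax[1]]], v = m[[ax[2]]]),
      ggplot2::aes(x = .data$h, y = .data$v),
      shape = 21, fill = "grey80", colour = "grey30", size = 2
    )
  }
  p
}

#' @method autoplot vist_scene
#' @export
autoplot.vist_scene <- function(object, ...) plot_vist_scene(object, ...)
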