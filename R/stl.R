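#' Export the fluid-solid interface as an STL surface
#'
#' Writes the staircase wall surface (the same set of voxel faces the WSS is
#' evaluated on) as an ASCII STL of two triangles per square face, for
#' visualization. If a `wss_field` is supplied, a sidecar CSV
#' (`<path>.csv`) carries the per-element positions and WSS so renderers
#' can colour the surface.
#'
#' @param domain a `fluid_domain` (or a `voxel_image` label image).
#' @param path output `.stl` path.
#' @param wss optional `wss_field` evaluated on the same domain.
#' @return `path`, invisibly.
#' @export
write_surface_stl <- function(domain, path, wss = NULL) {
  if (inherits(domain, "voxel_image")) domain <- build_fluid_domain(domain)
  if (!inherits(domain, "fluid_domain"))
    stop_pf("`domain` must be a fluid_domain or label voxel_image")
  el <- wall_face_table(domain)
  if (nrow(el) == 0L) stop_pf("no wall faces to export")
  h <- domain$voxel_size
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("solid poreflow_walls", con)
  tpl <- paste0(" facet normal %g %g %g\n  outer loop\n",
                "   vertex %g %g %g\n   vertex %g %g %g\n",
                "   vertex %g %g %g\n  endloop\n endfacet")
  for (r in seq_len(nrow(el))) {
    n <- c(el$nx[r], el$ny[r], el$nz[r])
    ctr <- c(el$x[r], el$y[r], el$z[r])
    tang <- which(n == 0)
    t1 <- c(0, 0, 0); t1[tang[1]] <- h / 2
    t2 <- c(0, 0, 0); t2[tang[2]] <- h / 2
    v1 <- ctr - t1 - t2; v2 <- ctr + t1 - t2
    v3 <- ctr + t1 + t2; v4 <- ctr - t1 + t2
    writeLines(sprintf(tpl, n[1], n[2], n[3], v1[1], v1[2], v1[3],
                       v2[1], v2[2], v2[3], v3[1], v3[2], v3[3]), con)
    writeLines(sprintf(tpl, n[1], n[2], n[3], v1[1], v1[2], v1[3],
                       v3[1], v3[2], v3[3], v4[1], v4[2], v4[3]), con)
  }
  writeLines("endsolid poreflow_walls", con)
  if (!is.null(wss))
    utils::write.csv(wss$elements, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

# wall-face table (positions/normals only) without a flow solution
wall_face_table <- function(domain) {
  m <- domain$mask
  h <- domain$voxel_size
  offs <- neighbour_offsets()
  rows <- list()
  for (r in seq_len(nrow(offs))) {
    e <- offs[r, ]
    nb <- shift_array(m, -e[1], -e[2], -e[3], fill = TRUE)
    wall <- m & !nb
    if (!any(wall)) next
    idx <- which(wall, arr.ind = TRUE)
    axis_n <- which(e != 0)
    pos <- (idx - 0.5) * h
    pos[, axis_n] <- pos[, axis_n] + sign(e[axis_n]) * h / 2
    rows[[length(rows) + 1L]] <- data.frame(
      x = domain$origin[1] + pos[, 1], y = domain$origin[2] + pos[, 2],
      z = domain$origin[3] + pos[, 3],
      nx = e[1], ny = e[2], nz = e[3], area = h^2)
  }
  if (length(rows) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      nx = integer(0), ny = integer(0), nz = integer(0),
                      area = numeric(0)))
  do.call(rbind, rows)
}
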