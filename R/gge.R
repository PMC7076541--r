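#' Entry-by-tester matrix of a diallel table
#'
#' In the GGE view of a diallel, every genotype is used both as an entry
#' (row) and as a tester (column); the cell is the mean of the
#' entry-by-tester cross, with the selfed-parent means on the diagonal.
#' The table must therefore include selfs (method-2 style data).
#'
#' @param x A `cross_means` table with the selfed diagonal present.
#' @return A plain symmetric `p x p` numeric matrix, rows = entries,
#'   columns = testers.
#' @export
build_entry_tester_matrix <- function(x) {
  if (anyNA(diag(x))) {
    abort(paste0("The entry-by-tester matrix needs selfed-parent means on ",
                 "the diagonal; use method-2 style data."))
  }
  matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

#' Center a two-way table by its tester (column) means
#'
#' Subtracts each column mean from the cells of that column, so that
#' every tester column of the adjusted matrix sums to zero. Only
#' centering is applied — no column standardization and no double
#' centering; row means of the result are in general nonzero.
#'
#' @param m Numeric matrix (entries x testers).
#' @return The column-centered matrix.
#' @export
center_by_tester <- function(m) {
  sweep(m, 2, colMeans(m))
}

#' GGE biplot model of a diallel table
#'
#' Rank-2 singular-value decomposition of the tester-centered
#' entry-by-tester matrix. Entry scores are `U %*% D^f` and tester scores
#' `V %*% D^(1-f)`; the symmetric default `f = 0.5` splits the singular
#' values evenly so entry-tester inner products are preserved under any
#' `f`. The average-tester-coordinate (ATC) axis points toward the mean
#' of the tester scores; entry projections on the ATC abscissa
#' approximate the parents' general combining ability and projections on
#' the ATC ordinate their specific combining ability.
#'
#' @param x A `cross_means` table with selfs, or a plain symmetric
#'   entry-by-tester matrix.
#' @param f Singular-value partition exponent in `[0, 1]` (default 0.5).
#' @return A `gge_biplot` object: `entry_scores`, `tester_scores` (p x 2),
#'   singular values `d`, `var_explained` per PC, the `atc` unit vector,
#'   a `projections` tibble (`entry`, `atc_abscissa`, `atc_ordinate`), the
#'   centered matrix, and a `degenerate` flag for zero input.
#' @export
gge_biplot <- function(x, f = 0.5) {
  if (f < 0 || f > 1) abort("`f` must lie in [0, 1].")
  m <- if (inherits(x, "cross_means")) build_entry_tester_matrix(x) else x
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("G", seq_len(nrow(m)))
  }
  centered <- center_by_tester(m)
  degenerate <- all(abs(centered) < 1e-12)
  if (degenerate) {
    warn("Centered matrix is zero; the biplot model is degenerate.")
  }
  sv <- svd(centered)
  d <- sv$d
  entry_scores <- sv$u[, 1:2, drop = FALSE] %*% diag(d[1:2]^f, 2)
  tester_scores <- sv$v[, 1:2, drop = FALSE] %*% diag(d[1:2]^(1 - f), 2)
  rownames(entry_scores) <- rownames(m)
  rownames(tester_scores) <- colnames(m)
  colnames(entry_scores) <- colnames(tester_scores) <- c("PC1", "PC2")
  var_explained <- if (sum(d^2) > 0) d[1:2]^2 / sum(d^2) else c(NA_real_, NA_real_)

  atc_raw <- colMeans(tester_scores)
  atc_len <- sqrt(sum(atc_raw^2))
  if (atc_len < 1e-12) {
    warn("Mean tester score is numerically zero; ATC direction undefined.")
    atc <- c(NA_real_, NA_real_)
    proj_a <- proj_o <- rep(NA_real_, nrow(m))
  } else {
    atc <- atc_raw / atc_len
    perp <- c(-atc[2], atc[1])
    proj_a <- drop(entry_scores %*% atc)
    proj_o <- drop(entry_scores %*% perp)
  }
  structure(
    list(
      entry_scores = entry_scores,
      tester_scores = tester_scores,
      d = d,
      var_explained = var_explained,
      atc = atc,
      projections = tibble::tibble(entry = rownames(m),
                                   atc_abscissa = proj_a,
                                   atc_ordinate = proj_o),
      centered = centered,
      f = f,
      degenerate = degenerate
    ),
    class = "gge_biplot"
  )
}

#' @export
print.gge_biplot <- function(x, ...) {
  cat("<gge_biplot> PC1", sprintf("%.1f%%", 100 * x$var_explained[1]),
      "PC2", sprintf("%.1f%%", 100 * x$var_explained[2]), "\n")
  print(x$projections)
  invisible(x)
}

#' @method tidy gge_biplot
#' @export
tidy.gge_biplot <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(role = "entry", name = rownames(x$entry_scores),
                   PC1 = x$entry_scores[, 1], PC2 = x$entry_scores[, 2]),
    tibble::tibble(role = "tester", name = rownames(x$tester_scores),
                   PC1 = x$tester_scores[, 1], PC2 = x$tester_scores[, 2])
  )
}

#' @method glance gge_biplot
#' @export
glance.gge_biplot <- function(x, ...) {
  tibble::tibble(
    pc1_var = x$var_explained[1],
    pc2_var = x$var_explained[2],
    f = x$f,
    degenerate = x$degenerate
  )
}

#' Which-won-where polygon view of a GGE biplot
#'
#' Draws the convex hull of the entry scores, splits the plane into
#' sectors by the rays from the origin perpendicular to each hull edge,
#' assigns every tester to the sector containing it, and names each
#' sector's hull vertex as its winning entry. For a diallel, a tester
#' falling in its own entry's sector means selfing beats crossing for
#' that parent, which the output flags.
#'
#' @param model A `gge_biplot`.
#' @return A `gge_polygon` object: `vertices` (hull entries in
#'   counterclockwise order) and a `sectors` tibble (`tester`, `winner`,
#'   `own_sector`).
#' @export
polygon_view <- function(model) {
  es <- model$entry_scores
  hull <- grDevices::chull(es[, 1], es[, 2])
  if (length(hull) < 3) {
    abort("Entry scores are collinear; no polygon view exists.")
  }
  hull <- rev(hull)  # chull is clockwise; use counterclockwise order
  verts <- es[hull, , drop = FALSE]
  k <- nrow(verts)
  # Boundary ray of the edge (v_t, v_{t+1}): direction perpendicular to
  # the edge, oriented so both endpoints have equal, positive projection.
  boundary_angle <- numeric(k)
  for (t in seq_len(k)) {
    a <- verts[t, ]
    b <- verts[t %% k + 1, ]
    w <- c(-(b - a)[2], (b - a)[1])
    if (sum(w * a) < 0) w <- -w
    boundary_angle[t] <- atan2(w[2], w[1])
  }
  # The sector of vertex t+1 is the angular wedge between the boundary
  # rays of its two adjacent edges (edges t and t+1, counterclockwise).
  ts <- model$tester_scores
  ccw <- function(from, to) (to - from) %% (2 * pi)
  assign_sector <- function(pt) {
    phi <- atan2(pt[2], pt[1])
    for (t in seq_len(k)) {
      t_next <- t %% k + 1
      if (ccw(boundary_angle[t], phi) <
          ccw(boundary_angle[t], boundary_angle[t_next])) {
        return(hull[t_next])
      }
    }
    # numerically on a boundary: fall back to the nearest boundary's vertex
    hull[which.min(abs(ccw(boundary_angle, phi)))]
  }
  sector_vertex <- apply(ts, 1, assign_sector)
  winner <- rownames(es)[sector_vertex]
  structure(
    list(
      vertices = rownames(es)[hull],
      hull_index = hull,
      boundary_angle = boundary_angle,
      sectors = tibble::tibble(
        tester = rownames(ts),
        winner = winner,
        own_sector = rownames(ts) == winner
      )
    ),
    class = "gge_polygon"
  )
}

#' @export
print.gge_polygon <- function(x, ...) {
  cat("<gge_polygon> vertices:", paste(x$vertices, collapse = ", "), "\n")
  print(x$sectors)
  invisible(x)
}

#' @param object A `gge_biplot`.
#' @param polygon Overlay the which-won-where hull and sector rays.
#' @param ... Unused.
#' @rdname gge_biplot
#' @method autoplot gge_biplot
#' @export
autoplot.gge_biplot <- function(object, polygon = FALSE, ...) {
  tbl <- tidy(object)
  pl <- ggplot2::ggplot(tbl, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name,
                                    colour = .data$role),
                       show.legend = TRUE) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      title = "GGE biplot of the diallel table"
    )
  if (!anyNA(object$atc)) {
    arrow_to <- object$atc * max(abs(tbl$PC1), abs(tbl$PC2))
    pl <- pl + ggplot2::annotate("segment", x = 0, y = 0,
                                 xend = arrow_to[1], yend = arrow_to[2],
                                 arrow = ggplot2::arrow(
                                   length = ggplot2::unit(2, "mm")),
                                 colour = "grey30")
  }
  if (polygon) {
    pv <- polygon_view(object)
    hv <- object$entry_scores[pv$hull_index, , drop = FALSE]
    hull_tbl <- tibble::tibble(PC1 = hv[, 1], PC2 = hv[, 2])
    pl <- pl + ggplot2::geom_polygon(data = hull_tbl, fill = NA,
                                     colour = "black", linewidth = 0.3)
    ray <- max(abs(c(tbl$PC1, tbl$PC2)))
    rays <- tibble::tibble(
      xend = ray * cos(pv$boundary_angle),
      yend = ray * sin(pv$boundary_angle)
    )
    pl <- pl + ggplot2::geom_segment(
      data = rays,
      ggplot2::aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend),
      inherit.aes = FALSE, colour = "red", linetype = 2, linewidth = 0.3
    )
  }
  pl
}
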