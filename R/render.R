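# Output renderings: the taxa-grouped conservation heatmap and the
# downloadable numerical results table.

#' Colour scales for the heatmap
#'
#' Similarity cells run from white (no sequence similarity, value 0) to
#' dark blue (very high similarity, value 1); the Pearson-r and Z-score
#' side columns run from pale yellow to dark red. Values outside the
#' mapped range are clamped.
#'
#' @param values Numeric vector.
#' @param range Value range mapped onto the ramp.
#' @return Character vector of hex colours.
#' @export
similarity_colors <- function(values, range = c(0, 1)) {
  ramp <- grDevices::colorRamp(c("#FFFFFF", "#08306B"))
  v <- pmin(pmax((values - range[1]) / diff(range), 0), 1)
  grDevices::rgb(ramp(v), maxColorValue = 255)
}

#' @rdname similarity_colors
#' @export
significance_colors <- function(values, range = c(0, 1)) {
  ramp <- grDevices::colorRamp(c("#FFFFCC", "#8B0000"))
  v <- pmin(pmax((values - range[1]) / diff(range), 0), 1)
  v[is.na(v)] <- 1  # the query's own row: maximal by definition
  grDevices::rgb(ramp(v), maxColorValue = 255)
}

#' Assemble the heatmap model for a query result
#'
#' Builds the displayable structure: the query's normalized profile as the
#' top row, followed by the top-k hits in rank order; genome columns in
#' manifest order with taxon group boundaries; Pearson r and permutation Z
#' as side columns (the query row carries r = 1 and no Z).
#'
#' @param hits An `npp_hits` object from [predict.npp()].
#' @return A `heatmap_model` list: `values` (rows x genomes, in `[0, 1]`),
#'   `r`, `z`, `row_labels`, `manifest`, `boundaries`.
#' @export
heatmap_model <- function(hits) {
  if (!inherits(hits, "npp_hits") || nrow(hits) == 0)
    npp_stop("hits must be a non-empty npp_hits object")
  manifest <- attr(hits, "manifest")
  qn <- attr(hits, "query_normalized")
  hn <- attr(hits, "normalized_hits")
  if (is.null(manifest) || is.null(qn) || is.null(hn))
    npp_stop("hits lack display attributes; use predict() on an npp fit")
  values <- rbind(query = qn, hn)
  rownames(values) <- c(attr(hits, "query"), hits$protein_id)
  structure(list(values = values,
                 r = c(1, hits$r), z = c(NA_real_, hits$z),
                 row_labels = rownames(values),
                 manifest = manifest,
                 boundaries = taxon_boundaries(manifest)),
            class = "heatmap_model")
}

# Draw a heatmap model on the current graphics device.
draw_heatmap <- function(model, main = NULL, z_range = c(0, 10)) {
  v <- model$values
  nr <- nrow(v); nc <- ncol(v)
  side <- 2                      # r and z columns
  gap <- 0.6
  op <- graphics::par(mar = c(7, 6, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, side + gap + nc), ylim = c(0, nr))
  ycell <- function(i) nr - i        # row 1 on top
  # side columns: r then z, yellow -> dark red
  for (i in seq_len(nr)) {
    graphics::rect(0, ycell(i), 1, ycell(i) + 1, border = "grey80",
                   col = significance_colors(model$r[i], range = c(0, 1)))
    graphics::rect(1, ycell(i), 2, ycell(i) + 1, border = "grey80",
                   col = significance_colors(model$z[i], range = z_range))
  }
  # similarity cells: white -> dark blue
  x0 <- side + gap
  cols <- similarity_colors(as.vector(t(v)))
  k <- 1L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    graphics::rect(x0 + j - 1, ycell(i), x0 + j, ycell(i) + 1,
                   border = NA, col = cols[k])
    k <- k + 1L
  }
  # taxon separators and labels on top
  for (bidx in model$boundaries)
    graphics::segments(x0 + bidx, 0, x0 + bidx, nr, col = "black", lwd = 1.5)
  runs <- rle(model$manifest$taxon)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  graphics::text(x0 + (starts + ends) / 2 - 0.5, nr + 0.02 * nr,
                 runs$values, xpd = NA, cex = 0.8, font = 2)
  graphics::text(c(0.5, 1.5), nr + 0.02 * nr, c("r", "Z"), xpd = NA,
                 cex = 0.8, font = 2)
  graphics::axis(2, at = seq_len(nr) - 0.5,
                 labels = rev(model$row_labels), las = 2, cex.axis = 0.5,
                 tick = FALSE)
  graphics::axis(1, at = x0 + seq_len(nc) - 0.5,
                 labels = model$manifest$species, las = 2, cex.axis = 0.4,
                 tick = FALSE)
  if (!is.null(main)) graphics::title(main = main)
  invisible(model)
}

#' Render a heatmap model to an image file
#'
#' Writes a PNG, SVG or PDF (chosen by the file extension) of the
#' taxa-grouped heatmap: query profile on top, hits below in rank order,
#' white-to-dark-blue similarity cells, yellow-to-dark-red r and Z side
#' columns, species names along the bottom and taxon separators.
#'
#' @param model A [heatmap_model()].
#' @param out_path Output path ending in `.png`, `.svg` or `.pdf`.
#' @param width,height Device size in pixels (png) or inches (svg/pdf).
#' @param ... Passed to `draw_heatmap` (e.g. `main`).
#' @return `out_path`, invisibly.
#' @export
render_heatmap <- function(model, out_path, width = NULL, height = NULL,
                           ...) {
  if (!inherits(model, "heatmap_model")) npp_stop("not a heatmap model")
  ext <- tolower(tools::file_ext(out_path))
  switch(ext,
         png = grDevices::png(out_path,
                              width = if (is.null(width)) 1400 else width,
                              height = if (is.null(height))
                                max(400, 24 * nrow(model$values) + 200)
                              else height),
         svg = grDevices::svg(out_path,
                              width = if (is.null(width)) 14 else width,
                              height = if (is.null(height)) 8 else height),
         pdf = grDevices::pdf(out_path,
                              width = if (is.null(width)) 14 else width,
                              height = if (is.null(height)) 8 else height),
         npp_stop("unsupported image format: '%s'", ext))
  on.exit(grDevices::dev.off())
  draw_heatmap(model, ...)
  invisible(out_path)
}

#' Heatmap plot of a query result
#'
#' Draws the taxa-grouped heatmap for an `npp_hits` object on the current
#' graphics device.
#' @param x An `npp_hits` object from [predict.npp()].
#' @param ... Passed to the drawing routine (e.g. `main`).
#' @return `x`, invisibly.
#' @export
plot.npp_hits <- function(x, ...) {
  draw_heatmap(heatmap_model(x), ...)
  invisible(x)
}

#' Write the downloadable results table
#'
#' Tab-separated table mirroring the server download: protein id, gene
#' name, short description, Pearson r, permutation Z-score, then one column
#' per genome holding the normalized similarity values of the profile. The
#' query appears as the first data row (rank 0, r = 1, empty Z).
#'
#' @param hits An `npp_hits` object from [predict.npp()].
#' @param out_path Output TSV path.
#' @param annotations Optional annotation `data.frame`
#'   ([read_annotations()]); proteins without an entry get empty name and
#'   description (with a warning).
#' @return The written `data.frame`, invisibly.
#' @export
write_results_table <- function(hits, out_path, annotations = NULL) {
  model <- heatmap_model(hits)
  ids <- model$row_labels
  ann <- data.frame(protein_id = ids, gene_name = "", description = "",
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    idx <- match(ids, annotations$protein_id)
    found <- !is.na(idx)
    ann$gene_name[found] <- annotations$gene_name[idx[found]]
    ann$description[found] <- annotations$description[idx[found]]
    if (any(!found))
      warning(sprintf("no annotation for %d protein(s)", sum(!found)),
              call. = FALSE)
  }
  df <- data.frame(rank = c(0, seq_len(nrow(hits))), ann,
                   r = model$r, z = model$z,
                   model$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(df)
}
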