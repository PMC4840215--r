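#' Electrode layout of a two-chamber microtunnel MEA
#'
#' Builds the 60-electrode geometry of an 8 x 8 grid (200 um pitch, corner
#' positions absent) carrying a two-chamber PDMS microtunnel device. Rows
#' 1-3 lie in the upstream chamber (Layer I, 22 electrodes), rows 4-5 run
#' inside the tunnel strip, and rows 6-8 lie in the downstream chamber
#' (Layer II, 22 electrodes). A subset of tunnels contains an electrode
#' pair separated by 200 um along the tunnel axis; because the tunnels are
#' pitched at 40 um against the 200 um electrode pitch, the number of
#' instrumented pairs is fixed by the device: 1 pair for the 2- and
#' 5-tunnel devices, 2 for 10 tunnels, 3 for 15 and 7 for 51.
#'
#' Electrode ids follow the column-then-row convention of commercial
#' 8 x 8 arrays (id "84" = column 8, row 4).
#'
#' @param n_tunnels number of physical tunnels; one of 2, 5, 10, 15, 51.
#' @return An object of class `mea_layout`: list with `electrodes`
#'   (data.frame: `electrode_id`, `grid_row`, `grid_col`, `region`),
#'   `tunnel_pairs` (data.frame: `upstream`, `downstream`,
#'   `separation_um`), `n_tunnels`, and `pitch_um` (200).
#' @export
make_layout <- function(n_tunnels) {
  pair_map <- c("2" = 1L, "5" = 1L, "10" = 2L, "15" = 3L, "51" = 7L)
  key <- as.character(n_tunnels)
  if (length(n_tunnels) != 1 || !key %in% names(pair_map))
    stop("unsupported n_tunnels: ", n_tunnels,
         " (supported devices have 2, 5, 10, 15 or 51 tunnels)")
  n_pairs <- pair_map[[key]]

  grid <- expand.grid(grid_col = 1:8, grid_row = 1:8)
  corner <- (grid$grid_row %in% c(1, 8)) & (grid$grid_col %in% c(1, 8))
  grid <- grid[!corner, ]
  grid$region <- ifelse(grid$grid_row <= 3, "LAYER1",
                 ifelse(grid$grid_row <= 5, "TUNNEL", "LAYER2"))
  grid$electrode_id <- paste0(grid$grid_col, grid$grid_row)
  grid <- grid[order(grid$grid_row, grid$grid_col),
               c("electrode_id", "grid_row", "grid_col", "region")]
  rownames(grid) <- NULL

  # instrumented tunnel columns, spread across the strip; row 4 faces Layer I
  pair_cols <- switch(key, "2" = 5L, "5" = 5L, "10" = c(3L, 6L),
                      "15" = c(2L, 5L, 7L), "51" = 2:8)
  pairs <- data.frame(upstream = paste0(pair_cols, 4),
                      downstream = paste0(pair_cols, 5),
                      separation_um = 200)

  structure(list(electrodes = grid, tunnel_pairs = pairs,
                 n_tunnels = as.integer(n_tunnels), pitch_um = 200),
            class = "mea_layout")
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("<mea_layout: %dT device, %d electrodes (%d/%d/%d L1/tunnel/L2), %d instrumented pair(s)>\n",
              x$n_tunnels, nrow(x$electrodes),
              sum(x$electrodes$region == "LAYER1"),
              sum(x$electrodes$region == "TUNNEL"),
              sum(x$electrodes$region == "LAYER2"),
              nrow(x$tunnel_pairs)))
  invisible(x)
}

#' Electrode ids belonging to one region of the layout
#' @param layout a [make_layout()] object.
#' @param region `"LAYER1"`, `"TUNNEL"` or `"LAYER2"`.
#' @export
layout_electrodes <- function(layout, region) {
  layout$electrodes$electrode_id[layout$electrodes$region == region]
}

#' Write / read a layout as JSON
#' @param layout a [make_layout()] object.
#' @param path file path.
#' @rdname layout_json
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$electrodes <- as.data.frame(obj$electrodes)
  obj$tunnel_pairs <- as.data.frame(obj$tunnel_pairs)
  structure(obj, class = "mea_layout")
}
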