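#' Compartment labels
#'
#' Closed enumeration of microfluidic compartments an electrode can sit in:
#' the two large somatic chambers, the short (proximal) and long (distal)
#' neurite microchannels, the middle synaptic chamber (neurite mixing, no
#' somas), the empty large chamber (axon outputs only) and `unassigned`.
#'
#' @return Character vector of valid compartment labels.
#' @export
compartment_labels <- function() {
  c("somatic_chamber_A", "somatic_chamber_B", "short_microchannel",
    "synaptic_chamber", "long_microchannel", "empty_chamber", "unassigned")
}

#' Default layout configuration
#'
#' Describes a 60-electrode commercial MEA (8 x 8 grid, 200 um pitch, four
#' corner positions absent) overlaid with a dual-compartment microfluidic
#' chip. Compartments are assigned by column ranges: columns 1-2 somatic
#' chamber, column 3 short microchannels, columns 4-5 synaptic chamber,
#' columns 6-7 long microchannels, column 8 empty chamber. Electrodes in
#' columns 1-4 are referenced against reference channel `R1` (closest to
#' the somatic chamber), columns 5-8 against `R2`.
#'
#' @return A list with elements `grid` (rows, cols, pitch_um, excluded),
#'   `compartments` (label -> c(col_from, col_to)) and `references`
#'   (reference-channel id -> integer vector of columns).
#' @export
default_layout_config <- function() {
  list(
    grid = list(
      rows = 8L, cols = 8L, pitch_um = 200,
      excluded = list(c(1L, 1L), c(1L, 8L), c(8L, 1L), c(8L, 8L))
    ),
    compartments = list(
      somatic_chamber_A  = c(1L, 2L),
      short_microchannel = c(3L, 3L),
      synaptic_chamber   = c(4L, 5L),
      long_microchannel  = c(6L, 7L),
      empty_chamber      = c(8L, 8L)
    ),
    references = list(R1 = 1:4, R2 = 5:8)
  )
}

#' Build an electrode layout
#'
#' Constructs and validates an `electrode_layout` from a configuration of
#' the form returned by [default_layout_config()]. Electrode ids follow the
#' commercial convention `<col><row>` (e.g. `"12"` is column 1, row 2);
#' rows and columns are 1-based; coordinates are micrometers from the
#' top-left grid position.
#'
#' @param config Layout configuration list (grid, compartments, references).
#' @return An object of class `electrode_layout`: a list with `n_rows`,
#'   `n_cols`, `pitch_um`, `excluded` (matrix of row/col pairs),
#'   `electrodes` (data.frame: id, row, col, x_um, y_um, compartment,
#'   reference), `reference_ids` and the originating `config`.
#' @export
#' @examples
#' lay <- build_layout()
#' nrow(lay$electrodes)  # 60
build_layout <- function(config = default_layout_config()) {
  g <- config$grid
  stopifnot(g$rows >= 1, g$cols >= 1, g$pitch_um > 0)
  excluded <- if (length(g$excluded)) {
    do.call(rbind, lapply(g$excluded, function(p) as.integer(p[1:2])))
  } else {
    matrix(integer(0), ncol = 2)
  }
  colnames(excluded) <- c("row", "col")

  grid <- expand.grid(row = seq_len(g$rows), col = seq_len(g$cols))
  if (nrow(excluded)) {
    keep <- !(paste(grid$row, grid$col) %in% paste(excluded[, 1], excluded[, 2]))
    grid <- grid[keep, , drop = FALSE]
  }

  # compartment from column ranges; overlaps and gaps are config errors
  comp <- config$compartments
  bad <- setdiff(names(comp), compartment_labels())
  if (length(bad)) stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
  col_owner <- rep(NA_character_, g$cols)
  for (lab in names(comp)) {
    rng <- comp[[lab]]
    cols <- seq.int(rng[1], rng[2])
    if (any(!is.na(col_owner[cols]))) {
      stop("configuration error: overlapping compartment ranges at column(s) ",
           paste(cols[!is.na(col_owner[cols])], collapse = ", "))
    }
    col_owner[cols] <- lab
  }
  if (anyNA(col_owner[unique(grid$col)])) {
    stop("configuration error: electrode column(s) ",
         paste(unique(grid$col)[is.na(col_owner[unique(grid$col)])], collapse = ", "),
         " assigned to no compartment")
  }

  refs <- config$references
  ref_owner <- rep(NA_character_, g$cols)
  for (r in names(refs)) ref_owner[refs[[r]]] <- r
  if (anyNA(ref_owner[unique(grid$col)])) {
    stop("configuration error: electrode column(s) without a reference channel")
  }

  electrodes <- data.frame(
    id = sprintf("%d%d", grid$col, grid$row),
    row = grid$row,
    col = grid$col,
    x_um = (grid$col - 1) * g$pitch_um,
    y_um = (grid$row - 1) * g$pitch_um,
    compartment = col_owner[grid$col],
    reference = ref_owner[grid$col],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(electrodes$id)) stop("duplicate electrode ids")
  if (any(electrodes$id %in% names(refs))) {
    stop("reference channel ids collide with electrode ids")
  }

  structure(
    list(n_rows = g$rows, n_cols = g$cols, pitch_um = g$pitch_um,
         excluded = excluded, electrodes = electrodes,
         reference_ids = names(refs), config = config),
    class = "electrode_layout"
  )
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("electrode_layout: %d x %d grid, %g um pitch, %d electrodes (%d excluded)\n",
              x$n_rows, x$n_cols, x$pitch_um, nrow(x$electrodes), nrow(x$excluded)))
  print(table(x$electrodes$compartment))
  invisible(x)
}

layout_lookup <- function(layout, id) {
  i <- match(id, layout$electrodes$id)
  if (anyNA(i)) stop("unknown electrode id: ", paste(id[is.na(i)], collapse = ", "))
  i
}

somatic_compartments <- function() c("somatic_chamber_A", "somatic_chamber_B")

#' Classify an electrode pair by compartment geometry
#'
#' Assigns the class used in the connectivity maps: `soma_neurite` when at
#' least one endpoint lies in a somatic chamber; otherwise `same_line` for
#' electrodes on the same grid row (within the same or an aligned
#' microchannel), `same_column` for the same column but different
#' microchannels, and `misaligned` for all remaining neurite-compartment
#' pairs. The classification is symmetric and total.
#'
#' @param layout An `electrode_layout`.
#' @param a,b Electrode ids; `a != b`.
#' @return One of `"soma_neurite"`, `"same_column"`, `"same_line"`,
#'   `"misaligned"`.
#' @export
edge_class <- function(layout, a, b) {
  if (any(a == b)) stop("edge_class requires two distinct electrodes")
  ia <- layout_lookup(layout, a)
  ib <- layout_lookup(layout, b)
  e <- layout$electrodes
  somatic <- e$compartment[ia] %in% somatic_compartments() |
    e$compartment[ib] %in% somatic_compartments()
  cls <- ifelse(somatic, "soma_neurite",
         ifelse(e$row[ia] == e$row[ib], "same_line",
         ifelse(e$col[ia] == e$col[ib], "same_column", "misaligned")))
  cls
}

#' Correlation span of an electrode pair, in pitches
#'
#' Chebyshev grid distance between two electrodes (the larger of row and
#' column offsets), i.e. the "n + k" length of a correlation arrow in units
#' of the electrode pitch.
#'
#' @inheritParams edge_class
#' @return Integer span in pitch units.
#' @export
edge_span <- function(layout, a, b) {
  ia <- layout_lookup(layout, a)
  ib <- layout_lookup(layout, b)
  e <- layout$electrodes
  pmax(abs(e$row[ia] - e$row[ib]), abs(e$col[ia] - e$col[ib]))
}

#' Electrode ordering used for correlation-matrix display
#'
#' Orders electrodes by compartment (in the order the configuration lists
#' them, matching the layout's color-bar convention), then by column, then
#' by row.
#'
#' @param layout An `electrode_layout`.
#' @return Character vector of electrode ids.
#' @export
compartment_order <- function(layout) {
  e <- layout$electrodes
  comp_rank <- match(e$compartment, names(layout$config$compartments))
  e$id[order(comp_rank, e$col, e$row)]
}

#' Write / read an electrode layout as JSON
#'
#' Serializes the layout *configuration* (grid, compartments, references);
#' reading rebuilds and revalidates the layout with [build_layout()].
#'
#' @param layout An `electrode_layout`.
#' @param path File path.
#' @return `write_layout_json` returns `path` invisibly; `read_layout_json`
#'   returns an `electrode_layout`.
#' @export
write_layout_json <- function(layout, path) {
  cfg <- layout$config
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$grid$excluded <- if (length(cfg$grid$excluded)) {
    lapply(seq_len(nrow(cfg$grid$excluded)), function(i) as.integer(cfg$grid$excluded[i, ]))
  } else {
    list()
  }
  cfg$compartments <- lapply(cfg$compartments, as.integer)
  cfg$references <- lapply(cfg$references, as.integer)
  build_layout(cfg)
}
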