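#' Model geometry: boxes, faces and vertical layers
#'
#' The spatial skeleton of the model is a set of polygonal boxes connected by
#' faces, with a shared vertical layer scheme truncated per box at its maximum
#' depth, plus one sediment layer. Boundary boxes carry externally prescribed
#' tracers and receive no internal state updates.
#'
#' @param boxes data.frame with columns `box_id`, `area` (m2), `max_depth` (m),
#'   `kind` ("dynamic" or "boundary"), habitat fraction columns
#'   `bedrock`, `sand`, `mud`, `manmade`, and a list-column `vertices` of
#'   two-column (lon, lat) matrices in counter-clockwise order.
#' @param faces data.frame with columns `face_id`, `left_box`, `right_box`,
#'   `length` (m). Exchange volumes are signed left-to-right positive.
#' @param layers list with `interface_depths` (strictly increasing water-layer
#'   bottom depths, m) and `sediment_thickness` (m).
#' @return An object of class `bs_geometry`.
#' @export
bs_geometry <- function(boxes, faces, layers) {
  geom <- structure(list(boxes = boxes, faces = faces, layers = layers),
                    class = "bs_geometry")
  validate_geometry(geom)
}

#' Validate a model geometry
#'
#' Enforces every structural invariant: positive areas, habitat fractions
#' summing to one, strictly increasing layer interfaces, faces referencing
#' existing distinct boxes, contiguous 0-based box ids, and at least one
#' dynamic box. Raises a validation error naming the offending record.
#'
#' @param geom a `bs_geometry`.
#' @return The geometry, invisibly usable, with derived fields attached:
#'   `n_layers`, per-box realized layer count `nlay`, and the per-box
#'   layer thickness matrix.
#' @export
validate_geometry <- function(geom) {
  b <- geom$boxes; f <- geom$faces; L <- geom$layers
  bs_validate(nrow(b) >= 1, "geometry has no boxes")
  bs_validate(identical(as.integer(b$box_id), seq_len(nrow(b)) - 1L),
              "box ids must be contiguous from 0")
  bs_validate(all(b$area > 0), sprintf(
    "non-positive area in box %s", paste(b$box_id[b$area <= 0], collapse = ",")))
  bs_validate(all(b$max_depth > 0), "non-positive max_depth")
  bs_validate(all(b$kind %in% c("dynamic", "boundary")),
              "box kind must be 'dynamic' or 'boundary'")
  bs_validate(any(b$kind == "dynamic"), "geometry needs at least one dynamic box")
  hsum <- rowSums(as.matrix(b[, HABITATS]))
  bad <- which(abs(hsum - 1) > 1e-9)
  bs_validate(length(bad) == 0, sprintf(
    "habitat fractions of box %s do not sum to 1", paste(b$box_id[bad], collapse = ",")))
  if (nrow(f) > 0) {
    bs_validate(all(f$left_box != f$right_box), sprintf(
      "face %s connects a box to itself",
      paste(f$face_id[f$left_box == f$right_box], collapse = ",")))
    ref <- c(f$left_box, f$right_box)
    miss <- setdiff(ref, b$box_id)
    if (length(miss) > 0) {
      badf <- f$face_id[f$left_box %in% miss | f$right_box %in% miss]
      bs_stop(sprintf("face %s references missing box %s",
                      paste(badf, collapse = ","), paste(miss, collapse = ",")),
              "baltisim_validation_error")
    }
  }
  z <- L$interface_depths
  bs_validate(length(z) >= 1 && all(diff(c(0, z)) > 0),
              "layer interface depths must be strictly increasing")
  bs_validate(L$sediment_thickness > 0, "sediment thickness must be > 0")

  geom$n_layers <- length(z)
  thick <- matrix(vapply(b$max_depth, function(d) layer_thicknesses(z, d),
                         numeric(length(z))),
                  nrow = nrow(b), ncol = length(z), byrow = TRUE)
  geom$thickness <- thick                       # [box, layer] m, 0 if absent
  geom$nlay <- rowSums(thick > 0)
  bs_validate(all(geom$nlay >= 1), "every box needs at least one realized layer")
  geom$volume <- thick * b$area                 # [box, layer] m3
  geom$dynamic <- which(b$kind == "dynamic")    # 1-based row indices
  geom$boundary <- which(b$kind == "boundary")
  geom
}

# thicknesses of realized layers for one box (deepest truncated at max_depth)
layer_thicknesses <- function(interfaces, max_depth) {
  top <- c(0, interfaces[-length(interfaces)])
  pmax(0, pmin(interfaces, max_depth) - pmin(top, max_depth))
}

#' Per-box realized layer volumes
#'
#' @param geom a validated `bs_geometry`.
#' @param box_id 0-based box id.
#' @return Numeric vector of m3, one entry per realized layer; their sum equals
#'   `area * max_depth` exactly.
#' @export
layer_volumes <- function(geom, box_id) {
  i <- match(box_id, geom$boxes$box_id)
  if (is.na(i)) bs_stop(sprintf("unknown box_id %s", box_id), "baltisim_lookup_error")
  v <- geom$volume[i, ]
  v[v > 0]
}

#' Read a geometry from its JSON serialization
#'
#' The on-disk schema (versioned, shipped with the package) holds `boxes`,
#' `faces` and `layers` records; areas are taken from the file, never
#' recomputed from vertices.
#'
#' @param path path to a geometry JSON file.
#' @return A validated `bs_geometry`.
#' @export
load_geometry <- function(path) {
  if (!file.exists(path)) bs_stop(sprintf("geometry file not found: %s", path),
                                  "baltisim_io_error")
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  boxes <- j$boxes
  boxes$vertices <- lapply(boxes$vertices, function(v) {
    m <- matrix(unlist(v), ncol = 2, byrow = FALSE)
    colnames(m) <- c("lon", "lat"); m
  })
  faces <- if (is.null(j$faces) || length(j$faces) == 0) {
    data.frame(face_id = integer(), left_box = integer(),
               right_box = integer(), length = numeric())
  } else as.data.frame(j$faces)
  layers <- list(interface_depths = as.numeric(j$layers$interface_depths),
                 sediment_thickness = as.numeric(j$layers$sediment_thickness))
  bs_geometry(boxes, faces, layers)
}

#' Write a geometry to JSON
#'
#' `load_geometry(write_geometry(g, p))` reproduces the structure
#' field-for-field.
#'
#' @param geom a validated `bs_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  b <- geom$boxes
  out <- list(
    schema_version = "1.0",
    boxes = lapply(seq_len(nrow(b)), function(i) list(
      box_id = b$box_id[i],
      vertices = unname(lapply(seq_len(nrow(b$vertices[[i]])),
                               function(k) as.numeric(b$vertices[[i]][k, ]))),
      area = b$area[i], max_depth = b$max_depth[i], kind = b$kind[i],
      bedrock = b$bedrock[i], sand = b$sand[i], mud = b$mud[i],
      manmade = b$manmade[i])),
    faces = lapply(seq_len(nrow(geom$faces)), function(i) as.list(geom$faces[i, ])),
    layers = list(interface_depths = geom$layers$interface_depths,
                  sediment_thickness = geom$layers$sediment_thickness))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Built-in exemplar geometries
#'
#' Two geometries ship with the package. `"baltic29"` reproduces the counts and
#' qualitative connectivity of the full domain: 29 polygon boxes (26 dynamic,
#' 3 boundary), 100 faces, eight water layers
#' (0-5, 5-10, 10-30, 30-40, 40-50, 50-100, 100-200, >200 m) and a 0.5 m
#' sediment layer. Polygon vertex coordinates are schematic (the true shapes
#' are not published); areas and depths are plausible basin-scale values.
#' `"mini8"` is a reduced whole-basin test geometry: 8 boxes (1 boundary,
#' 4 coastal, 3 offshore) and 3 water layers, used by the fast test suite and
#' the shipped exemplar runs.
#'
#' @param name `"baltic29"` or `"mini8"`.
#' @return A validated `bs_geometry`.
#' @export
example_geometry <- function(name = c("mini8", "baltic29")) {
  name <- match.arg(name)
  if (name == "mini8") mini8_geometry() else baltic29_geometry()
}

# rectangle vertex helper (counter-clockwise)
rect_vertices <- function(lon0, lat0, dlon = 1, dlat = 1) {
  matrix(c(lon0, lat0, lon0 + dlon, lat0, lon0 + dlon, lat0 + dlat,
           lon0, lat0 + dlat), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("lon", "lat")))
}

mini8_geometry <- function() {
  # box 0: boundary (Kattegat opening); 1-4 coastal; 5-7 offshore deep basins
  kind <- c("boundary", rep("dynamic", 7))
  depth <- c(80, 25, 25, 30, 25, 80, 80, 60)
  area <- c(2e10, 3e10, 4e10, 3e10, 3e10, 9e10, 1.1e11, 6e10)
  hab <- rbind(
    c(0.05, 0.60, 0.35, 0.00),
    c(0.10, 0.55, 0.30, 0.05),
    c(0.05, 0.50, 0.45, 0.00),
    c(0.15, 0.45, 0.40, 0.00),
    c(0.05, 0.55, 0.40, 0.00),
    c(0.00, 0.20, 0.80, 0.00),
    c(0.00, 0.15, 0.85, 0.00),
    c(0.00, 0.25, 0.75, 0.00))
  boxes <- data.frame(box_id = 0:7, area = area, max_depth = depth,
                      kind = kind, bedrock = hab[, 1], sand = hab[, 2],
                      mud = hab[, 3], manmade = hab[, 4])
  boxes$vertices <- lapply(0:7, function(i) rect_vertices(10 + 2 * i, 54 + i))
  edges <- rbind(
    c(0, 1), c(0, 5), c(0, 6), # boundary: coastal entrance + deep basins
    c(1, 2), c(2, 3), c(3, 4), # coastal chain
    c(1, 5), c(2, 5), c(2, 6), c(3, 6), c(4, 7), # coastal-offshore
    c(5, 6), c(6, 7))          # offshore chain
  faces <- data.frame(face_id = seq_len(nrow(edges)) - 1L,
                      left_box = edges[, 1], right_box = edges[, 2],
                      length = 6e4)
  bs_geometry(boxes, faces,
              list(interface_depths = c(10, 30, 80), sediment_thickness = 0.5))
}

baltic29_geometry <- function() {
  n <- 29
  kind <- rep("dynamic", n); kind[c(1, 28, 29)] <- "boundary"  # boxes 0, 27, 28
  set_d <- rep(c(25, 60, 90, 150, 45, 220, 70, 35, 55), length.out = n)
  area <- rep(c(6e9, 1.4e10, 2.2e10, 1.8e10, 9e9, 2.6e10, 1.2e10), length.out = n)
  hab <- t(vapply(seq_len(n), function(i) {
    h <- c(0.05 + (i %% 3) * 0.05, 0.35, 0, 0.02)
    h[3] <- 1 - sum(h[c(1, 2, 4)]); h
  }, numeric(4)))
  boxes <- data.frame(box_id = 0:(n - 1), area = area, max_depth = set_d,
                      kind = kind, bedrock = hab[, 1], sand = hab[, 2],
                      mud = hab[, 3], manmade = hab[, 4])
  boxes$vertices <- lapply(seq_len(n) - 1, function(i)
    rect_vertices(9 + (i %% 6) * 2.5, 53.5 + (i %/% 6) * 1.6))
  # deterministic connectivity: chain + second-neighbour chords + boundary
  # attachments, padded with longer-range chords to exactly 100 faces
  edges <- cbind(0:(n - 2), 1:(n - 1))
  edges <- rbind(edges, cbind(0:(n - 3), 2:(n - 1)))
  edges <- rbind(edges, cbind(0:(n - 4), 3:(n - 1)))
  edges <- rbind(edges, cbind(0:(n - 5), 4:(n - 1)))
  edges <- edges[!duplicated(paste(edges[, 1], edges[, 2])), ]
  stopifnot(nrow(edges) >= 100)
  edges <- edges[seq_len(100), ]
  faces <- data.frame(face_id = 0:99, left_box = edges[, 1],
                      right_box = edges[, 2], length = 5e4)
  bs_geometry(boxes, faces,
              list(interface_depths = c(5, 10, 30, 40, 50, 100, 200, 450),
                   sediment_thickness = 0.5))
}
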