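# small synthetic geometries used across the test suite

two_box_geometry <- function(kind = c("dynamic", "dynamic"), depth = c(10, 10),
                             area = c(1e6, 1e6), two_faces = FALSE) {
  boxes <- data.frame(box_id = 0:1, area = area, max_depth = depth,
                      kind = kind, bedrock = 0, sand = 0.5, mud = 0.5,
                      manmade = 0)
  boxes$vertices <- lapply(0:1, function(i)
    matrix(c(i, 0, i + 1, 0, i + 1, 1, i, 1), ncol = 2, byrow = TRUE))
  faces <- if (two_faces) {
    data.frame(face_id = 0:1, left_box = c(0L, 1L), right_box = c(1L, 0L),
               length = 1e3)
  } else {
    data.frame(face_id = 0L, left_box = 0L, right_box = 1L, length = 1e3)
  }
  bs_geometry(boxes, faces,
              list(interface_depths = max(depth), sediment_thickness = 0.5))
}

column_geometry <- function(interfaces = c(5, 10, 15), depth = NULL,
                            area = 1e6) {
  if (is.null(depth)) depth <- max(interfaces)
  boxes <- data.frame(box_id = 0L, area = area, max_depth = depth,
                      kind = "dynamic", bedrock = 0, sand = 0.5, mud = 0.5,
                      manmade = 0)
  boxes$vertices <- list(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2,
                                byrow = TRUE))
  faces <- data.frame(face_id = integer(), left_box = integer(),
                      right_box = integer(), length = numeric())
  bs_geometry(boxes, faces,
              list(interface_depths = interfaces, sediment_thickness = 0.5))
}

# groups configuration with fishing and natural vertebrate mortality off,
# used by the closed-system conservation tests
zero_f_groups <- function() {
  gr <- default_groups()
  for (v in names(gr$verts)) {
    gr$verts[[v]]$F_adult_yr <- 0
    gr$verts[[v]]$F_juv_yr <- 0
  }
  gr
}
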