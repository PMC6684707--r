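#' Face interest-area layout
#'
#' Defines the interest areas (IAs) used to classify fixations on a face
#' image: axis-aligned rectangles for the four inner regions (left eye,
#' right eye, nose, mouth) inside a face bounding box, plus anchor points
#' for the outer landmarks used by the fixed-sequence countermeasure
#' (forehead, ears, chin). "Left"/"right" are the face's own left/right, so
#' the *right* eye sits in the viewer's left visual field.
#'
#' No published pixel geometry exists for these regions, so the layout is a
#' documented, reproducible default expressed as proportions of the face
#' box and fully overridable: eyes are 18% x 12% rectangles centred at
#' 30%/70% of the width and 40% of the height, the nose 20% x 18% at the
#' centre, the mouth 30% x 12% at 75% height.
#'
#' @param image_px `c(width, height)` of the face image in pixels.
#' @param screen_px `c(width, height)` of the screen; the image is centred.
#' @param eye_size,nose_size,mouth_size Region sizes as proportions
#'   `c(width, height)` of the face box.
#' @param eye_y,mouth_y Vertical centres as proportions of box height.
#' @param eye_x Horizontal centres of the two eyes (right eye first).
#' @return An object of class `"face_layout"`: list with `box` (xmin, xmax,
#'   ymin, ymax), `regions` (named list of rectangles, in priority order)
#'   and `anchors` (named 2-column matrix of landmark points).
#' @examples
#' lay <- face_layout()
#' lay$box
#' @export
face_layout <- function(image_px = c(595L, 420L), screen_px = c(1440L, 900L),
                        eye_size = c(0.18, 0.12), nose_size = c(0.20, 0.18),
                        mouth_size = c(0.30, 0.12), eye_y = 0.40,
                        mouth_y = 0.75, eye_x = c(0.30, 0.70)) {
  if (any(image_px <= 0) || any(screen_px <= 0))
    stop_bad_arg("image_px", "image and screen sizes must be positive")
  w <- image_px[1]; h <- image_px[2]
  x0 <- (screen_px[1] - w) / 2
  y0 <- (screen_px[2] - h) / 2
  box <- c(xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h)
  rect_at <- function(cx, cy, size) {
    c(xmin = x0 + (cx - size[1] / 2) * w, xmax = x0 + (cx + size[1] / 2) * w,
      ymin = y0 + (cy - size[2] / 2) * h, ymax = y0 + (cy + size[2] / 2) * h)
  }
  regions <- list(
    right_eye = rect_at(eye_x[1], eye_y, eye_size),
    left_eye  = rect_at(eye_x[2], eye_y, eye_size),
    nose      = rect_at(0.50, 0.50, nose_size),
    mouth     = rect_at(0.50, mouth_y, mouth_size)
  )
  pt <- function(cx, cy) c(x = x0 + cx * w, y = y0 + cy * h)
  anchors <- rbind(forehead  = pt(0.50, 0.08),
                   right_ear = pt(0.04, 0.45),
                   right_eye = pt(eye_x[1], eye_y),
                   left_eye  = pt(eye_x[2], eye_y),
                   left_ear  = pt(0.96, 0.45),
                   nose      = pt(0.50, 0.50),
                   mouth     = pt(0.50, mouth_y),
                   chin      = pt(0.50, 0.97))
  layout <- structure(list(box = box, regions = regions, anchors = anchors),
                      class = "face_layout")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  for (nm in names(layout$regions)) {
    r <- layout$regions[[nm]]
    if (r["xmin"] >= r["xmax"] || r["ymin"] >= r["ymax"])
      stop_bad_arg("layout", sprintf("region %s is degenerate", nm))
    if (r["xmin"] < layout$box["xmin"] || r["xmax"] > layout$box["xmax"] ||
        r["ymin"] < layout$box["ymin"] || r["ymax"] > layout$box["ymax"])
      stop_bad_arg("layout", sprintf("region %s leaves the face box", nm))
  }
  # inner regions must be pairwise disjoint
  nms <- names(layout$regions)
  for (i in seq_along(nms)) for (j in seq_len(i - 1L)) {
    a <- layout$regions[[i]]; b <- layout$regions[[j]]
    if (a["xmin"] < b["xmax"] && b["xmin"] < a["xmax"] &&
        a["ymin"] < b["ymax"] && b["ymin"] < a["ymax"])
      stop_bad_arg("layout", sprintf("regions %s and %s overlap",
                                     nms[i], nms[j]))
  }
  invisible(layout)
}

#' Assign fixation centroids to interest areas
#'
#' Point-in-rectangle test against the inner regions in priority order;
#' centroids inside the face box but in no inner rectangle are `"outer"`,
#' centroids off the face box are `"off_face"`. The assignment is
#' deterministic and total.
#'
#' @param x,y Centroid coordinates in pixels (vectorised).
#' @param layout A [face_layout()].
#' @return Character vector of labels among `left_eye`, `right_eye`,
#'   `nose`, `mouth`, `outer`, `off_face`.
#' @examples
#' lay <- face_layout()
#' assign_region(720, 450, lay)  # face centre -> nose
#' assign_region(0, 0, lay)      # screen corner -> off_face
#' @export
assign_region <- function(x, y, layout = face_layout()) {
  if (!inherits(layout, "face_layout"))
    stop_bad_arg("layout", "must be a face_layout object")
  if (length(x) != length(y))
    stop_bad_arg("x", "x and y must have equal length")
  lab <- rep("off_face", length(x))
  b <- layout$box
  on_face <- x >= b["xmin"] & x <= b["xmax"] & y >= b["ymin"] & y <= b["ymax"]
  lab[on_face] <- "outer"
  for (nm in names(layout$regions)) {
    r <- layout$regions[[nm]]
    hit <- lab == "outer" &
      x >= r["xmin"] & x <= r["xmax"] & y >= r["ymin"] & y <= r["ymax"]
    lab[hit] <- nm
  }
  lab
}

# Region label sets used by the marker module.
INNER_REGIONS <- c("left_eye", "right_eye", "nose", "mouth")
EYE_REGIONS <- c("left_eye", "right_eye")
IA_CATEGORIES <- c("left_eye", "right_eye", "nose", "mouth", "outer")

#' @export
print.face_layout <- function(x, ...) {
  b <- x$box
  cat(sprintf("Face layout: box [%g, %g] x [%g, %g] px; inner regions: %s\n",
              b["xmin"], b["xmax"], b["ymin"], b["ymax"],
              paste(names(x$regions), collapse = ", ")))
  invisible(x)
}
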