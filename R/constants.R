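# Shared conventions for the eleven LV indices.
#
# Orientation: angle 0 points image-right (+col), angles increase
# counter-clockwise (towards decreasing row). Short-axis LV-Quan images are
# pre-rotated to a canonical pose, so the six anatomical segments are fixed
# directions: the anterior (A) bisector points up, and the remaining
# bisectors follow every 60 degrees.

#' Names of the eleven LV quantification indices
#'
#' Two normalized areas, three cavity dimensions (IS-AL, I-A and IL-AS
#' directions) and six regional wall thicknesses in the order IS, I, IL,
#' AL, A, AS.
#' @export
lvq_index_names <- c("area_cav", "area_myo", "dim1", "dim2", "dim3",
                     "rwt_is", "rwt_i", "rwt_il", "rwt_al", "rwt_a", "rwt_as")

#' Segment bisector angles (radians)
#'
#' Bisector direction of each myocardial segment under the package's fixed
#' orientation convention (anterior at 90 degrees, counter-clockwise).
#' @export
lvq_segment_angles <- c(is = 210, i = 270, il = 330,
                        al = 30, a = 90, as = 150) * pi / 180

# Axis direction of each cavity dimension (full line through the centroid):
# dim1 = IS-AL, dim2 = I-A, dim3 = IL-AS.
lvq_dim_angles <- c(dim1 = 210, dim2 = 270, dim3 = 330) * pi / 180

#' Column schema of a per-subject index table (indices.csv)
#' @export
lvq_csv_columns <- c("frame", lvq_index_names, "phase")

# Default pixel spacing (mm/pixel): the mode of the LV-Quan acquisitions.
lvq_default_spacing <- 1.5625

# Displacement of a point at polar angle `theta`, radius `r` from `center`
# (0-based (row, col), pixel centers at integers).
polar_point <- function(center, r, theta) {
  cbind(row = center[1] - r * sin(theta), col = center[2] + r * cos(theta))
}
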