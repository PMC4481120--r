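#' Landmark scheme
#'
#' A landmark scheme describes the biological landmarks of a study: their
#' ids, names, whether they lie on the midline or on both sides of the
#' specimen, and their type (type I = intersection of tissue boundaries such
#' as bone sutures; type II = point of maximal curvature such as a bone tip).
#' Bilateral landmarks share one id between the left and the right side; the
#' side is carried separately.
#'
#' @param entries a data frame with columns `landmark` (integer id, unique
#'   and contiguous from 1), `name` (character), `position` (one of
#'   `"midline"`, `"bilateral"`) and `type` (`"I"` or `"II"`).
#' @return An object of class `landmark_scheme`: the validated data frame.
#' @seealso [default_landmark_scheme()], [expand_sides()]
#' @export
landmark_scheme <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  required <- c("landmark", "name", "position", "type")
  if (!all(required %in% names(entries)))
    stop("landmark scheme needs columns: ", paste(required, collapse = ", "))
  entries$landmark <- as.integer(entries$landmark)
  if (anyDuplicated(entries$landmark))
    stop("duplicated landmark ids in scheme")
  if (!identical(sort(entries$landmark), seq_len(nrow(entries))))
    stop("landmark ids must be contiguous integers starting at 1")
  if (!all(entries$position %in% c("midline", "bilateral")))
    stop("position must be 'midline' or 'bilateral'")
  if (!all(entries$type %in% c("I", "II")))
    stop("landmark type must be 'I' or 'II'")
  entries <- entries[order(entries$landmark), , drop = FALSE]
  rownames(entries) <- NULL
  class(entries) <- c("landmark_scheme", "data.frame")
  entries
}

#' Distance scheme
#'
#' A distance scheme lists the inter-landmark distances of interest: pairs of
#' landmark ids with a label (typically the bone the distance measures).
#' Distances whose endpoints include a bilateral landmark exist on both sides
#' and are averaged across sides by [average_bilateral()].
#'
#' @param entries a data frame with columns `distance` (integer id, unique),
#'   `landmark_a`, `landmark_b` (landmark ids) and `label` (character).
#' @param scheme optional [landmark_scheme()] used to check that referenced
#'   landmark ids exist.
#' @return An object of class `distance_scheme`.
#' @export
distance_scheme <- function(entries, scheme = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  required <- c("distance", "landmark_a", "landmark_b", "label")
  if (!all(required %in% names(entries)))
    stop("distance scheme needs columns: ", paste(required, collapse = ", "))
  entries$distance <- as.integer(entries$distance)
  entries$landmark_a <- as.integer(entries$landmark_a)
  entries$landmark_b <- as.integer(entries$landmark_b)
  if (anyDuplicated(entries$distance))
    stop("duplicated distance ids in scheme")
  if (any(entries$landmark_a == entries$landmark_b))
    stop("a distance must join two distinct landmarks")
  if (!is.null(scheme)) {
    ids <- scheme$landmark
    bad <- setdiff(c(entries$landmark_a, entries$landmark_b), ids)
    if (length(bad))
      stop("distance scheme references unknown landmark ids: ",
           paste(bad, collapse = ", "))
  }
  entries <- entries[order(entries$distance), , drop = FALSE]
  rownames(entries) <- NULL
  class(entries) <- c("distance_scheme", "data.frame")
  entries
}

#' Canonical side expansion of a landmark scheme
#'
#' Bilateral landmarks occupy two rows of a configuration matrix (left and
#' right). The canonical row order is: all midline landmarks in ascending id
#' order, then all left-side landmarks in ascending id order, then all
#' right-side landmarks in ascending id order. This mapping depends only on
#' the scheme, never on the order rows happen to appear in a file.
#'
#' @param scheme a [landmark_scheme()].
#' @return A data frame with one row per configuration-matrix row: columns
#'   `index` (row in the coordinate matrix), `landmark` (id) and `side`
#'   (`"M"`, `"L"` or `"R"`).
#' @export
expand_sides <- function(scheme) {
  mid <- scheme$landmark[scheme$position == "midline"]
  bil <- scheme$landmark[scheme$position == "bilateral"]
  out <- data.frame(
    landmark = c(sort(mid), sort(bil), sort(bil)),
    side = c(rep("M", length(mid)), rep("L", length(bil)),
             rep("R", length(bil))),
    stringsAsFactors = FALSE
  )
  out <- cbind(index = seq_len(nrow(out)), out)
  out
}

#' Number of side-expanded landmarks of a scheme
#' @param scheme a [landmark_scheme()].
#' @return Integer: midline count + 2 x bilateral count.
#' @export
n_expanded <- function(scheme) {
  sum(scheme$position == "midline") + 2L * sum(scheme$position == "bilateral")
}

#' Default toad-skull landmark and distance schemes
#'
#' The bundled scheme describes 20 cranial landmarks (5 midline, 15
#' bilateral; 35 points after side expansion) placed at bone sutures (type I)
#' or bone tips (type II: landmarks 1, 14, 15 and 19), and 24 inter-landmark
#' distances representing individual bone dimensions (plus the orbit).
#'
#' @return A list with elements `landmarks` (a [landmark_scheme()]) and
#'   `distances` (a [distance_scheme()]).
#' @examples
#' sch <- default_schemes()
#' nrow(sch$landmarks)      # 20
#' n_expanded(sch$landmarks) # 35
#' @export
default_schemes <- function() {
  lm <- landmark_scheme(data.frame(
    landmark = 1:20,
    name = c(
      "anterior tip of nasal bone",
      "nasal and frontoparietal suture",
      "posterior tip of frontoparietal suture",
      "nasal and maxillary suture",
      "nasal and frontoparietal lateral suture",
      "frontoparietal and squamosal suture",
      "frontoparietal, squamosal and occipital suture",
      "squamosal and occipital suture",
      "frontoparietal and occipital suture",
      "prenasal and maxillary lateral suture",
      "nasal and maxillary lateral suture",
      "squamosal and maxillary suture",
      "sphenethmoid and parasphenoid suture",
      "posterior tip of parasphenoid corpus",
      "anterior tip of premaxillary bone",
      "premaxillary and maxillary suture",
      "pterygoid and maxillary suture",
      "neopalatine and sphenethmoid suture",
      "tip of pterygoid process",
      "pterygoid and parasphenoid suture"
    ),
    position = ifelse(1:20 %in% c(1, 2, 3, 13, 14), "midline", "bilateral"),
    type = ifelse(1:20 %in% c(1, 14, 15, 19), "II", "I"),
    stringsAsFactors = FALSE
  ))
  ds <- distance_scheme(data.frame(
    distance = 1:24,
    landmark_a = c(1, 2, 1, 1, 2, 5, 4, 6, 7, 3, 1, 1,
                   10, 5, 10, 8, 13, 13, 15, 16, 17, 17, 19, 14),
    landmark_b = c(2, 3, 4, 5, 5, 6, 6, 8, 9, 9, 10, 11,
                   11, 11, 12, 12, 14, 20, 16, 17, 18, 19, 20, 20),
    label = c("nasal", "frontoparietal", "nasal", "nasal", "frontoparietal",
              "frontoparietal", "orbit", "squamosal", "occipital",
              "frontoparietal", "prenasal", "nasal", "nasal", "nasal",
              "maxilla", "squamosal", "parasphenoid", "parasphenoid",
              "premaxilla", "nasal", "neopalatine", "pterygoid",
              "pterygoid", "parasphenoid"),
    stringsAsFactors = FALSE
  ), scheme = lm)
  list(landmarks = lm, distances = ds)
}

#' @rdname default_schemes
#' @export
default_landmark_scheme <- function() default_schemes()$landmarks

#' @rdname default_schemes
#' @export
default_distance_scheme <- function() default_schemes()$distances
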