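#' Genomic location values
#'
#' A location is a closed interval on a named chromosome of one organism,
#' expressed either on the physical map (unit `"bp"`) or a genetic map
#' (unit `"cM"`). Locations are only ever compared when chromosome, unit
#' and taxid all agree: co-location of datasets is meaningful only when
#' they are based on the same physical or genetic map. Coordinates follow
#' the GFF3 convention graph-wide: 1-based with inclusive ends. Point
#' positions (SNPs, cM point estimates) have `begin == end`.
#'
#' @param chromosome chromosome label (e.g. `"5H"`).
#' @param begin,end coordinates, `1 <= begin <= end` (cM values may be
#'   fractional; the lower bound applies to bp only).
#' @param unit `"bp"` or `"cM"`.
#' @param taxid organism taxonomy id (character).
#' @return list of class `gsknet_location`.
#' @examples
#' genomic_location("5H", 40, 55, "cM", "112509")
#' @export
genomic_location <- function(chromosome, begin, end = begin, unit = c("bp", "cM"),
                             taxid = "0") {
  unit <- match.arg(unit)
  begin <- as.numeric(begin); end <- as.numeric(end)
  if (is.na(begin) || is.na(end) || end < begin)
    graph_error("invalid location: begin %s, end %s", begin, end)
  if (unit == "bp" && begin < 1)
    graph_error("bp coordinates are 1-based; got begin = %s", begin)
  structure(list(chromosome = as.character(chromosome), begin = begin,
                 end = end, unit = unit, taxid = as.character(taxid)),
            class = "gsknet_location")
}

is_location <- function(x) inherits(x, "gsknet_location")

# frame key under which locations are comparable
loc_frame <- function(loc) idx_key(loc$chromosome, loc$unit, loc$taxid)

# collect (concept id, location) pairs for a class; a concept may carry both
# a physical and a genetic-map location
gather_locations <- function(g, class,
                             attributes = c("Location", "GenMapLocation")) {
  out <- list()
  for (k in ls(g$concepts)) {
    con <- g$concepts[[k]]
    if (con$class != class) next
    for (a in attributes) {
      loc <- con$attributes[[a]]
      if (is.null(loc)) next
      if (!is_location(loc))
        graph_error("attribute %s of concept %s is not a location", a, con$id)
      if (!(loc$unit %in% c("bp", "cM")))
        graph_error("location with unknown unit '%s' on concept %s", loc$unit, con$id)
      out[[length(out) + 1L]] <- list(id = con$id, loc = loc)
    }
  }
  out
}
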