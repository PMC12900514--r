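#' rDNA unit annotation
#'
#' An `rdna_annotation` is a partition of the 35S transcription unit into
#' named, contiguous, non-overlapping regions given in 1-based inclusive
#' coordinates on the sense strand. The first region must start at 1 and the
#' last must end at `unit_length`, so that every position belongs to exactly
#' one region.
#'
#' @param regions data.frame with columns `name` (character), `start`, `end`
#'   (1-based inclusive integer positions).
#' @param unit_length total length of the unit in nt; defaults to
#'   `max(regions$end)`.
#' @return an object of class `rdna_annotation`: a data.frame of regions with
#'   attribute `unit_length`.
#' @seealso [default_annotation()], [region_of()]
#' @export
rdna_annotation <- function(regions, unit_length = max(regions$end)) {
  stopifnot(is.data.frame(regions), all(c("name", "start", "end") %in% names(regions)))
  regions <- data.frame(
    name  = as.character(regions$name),
    start = as.integer(regions$start),
    end   = as.integer(regions$end),
    stringsAsFactors = FALSE
  )
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  unit_length <- as.integer(unit_length)
  if (any(is.na(regions$start)) || any(is.na(regions$end)))
    stop("region coordinates must be integers")
  if (any(regions$start > regions$end))
    stop("region start must not exceed end")
  if (anyDuplicated(regions$name))
    stop("region names must be unique")
  if (regions$start[1L] != 1L)
    stop("first region must start at position 1")
  if (regions$end[nrow(regions)] != unit_length)
    stop("last region must end at unit_length (", unit_length, ")")
  if (nrow(regions) > 1L) {
    gap <- regions$start[-1L] != regions$end[-nrow(regions)] + 1L
    if (any(gap))
      stop("regions must be contiguous; break after '",
           regions$name[which(gap)[1L]], "'")
  }
  structure(regions, unit_length = unit_length,
            class = c("rdna_annotation", "data.frame"))
}

#' Unit length of an annotation
#' @param annotation an [rdna_annotation()].
#' @return integer length of the unit in nt.
#' @export
unit_length <- function(annotation) {
  attr(annotation, "unit_length")
}

#' Default 35S rDNA annotation
#'
#' The seven-region map of the yeast 35S unit: 5'ETS 1-700, 18S 701-2499,
#' ITS1 2500-2858, 5.8S 2859-3019, ITS2 3020-3250, 25S 3251-6647 and
#' 3'ETS 6648-6859, for a unit of 6859 nt.
#'
#' @return an [rdna_annotation()] of the seven canonical regions.
#' @examples
#' ann <- default_annotation()
#' unit_length(ann)
#' region_of(ann, 700)
#' @export
default_annotation <- function() {
  rdna_annotation(data.frame(
    name  = c("5'ETS", "18S", "ITS1", "5.8S", "ITS2", "25S", "3'ETS"),
    start = c(1L, 701L, 2500L, 2859L, 3020L, 3251L, 6648L),
    end   = c(700L, 2499L, 2858L, 3019L, 3250L, 6647L, 6859L)
  ))
}

#' Region containing a position
#'
#' @param annotation an [rdna_annotation()].
#' @param position 1-based position(s) within the unit.
#' @return character vector of region names, one per position.
#' @export
region_of <- function(annotation, position) {
  stopifnot(inherits(annotation, "rdna_annotation"))
  position <- as.integer(position)
  L <- unit_length(annotation)
  bad <- is.na(position) | position < 1L | position > L
  if (any(bad))
    stop("position out of bounds [1, ", L, "]: ", position[bad][1L])
  idx <- findInterval(position, annotation$start)
  annotation$name[idx]
}

#' Positions covered by a named region
#' @param annotation an [rdna_annotation()].
#' @param name region name.
#' @return integer vector of positions `start:end`.
#' @export
region_positions <- function(annotation, name) {
  i <- match(name, annotation$name)
  if (is.na(i)) stop("unknown region: ", name)
  seq.int(annotation$start[i], annotation$end[i])
}

#' Read / write annotations
#'
#' Native format is a header-bearing TSV with columns `name`, `start`, `end`
#' in 1-based inclusive coordinates; the partition invariants are checked at
#' load. `write_annotation_bed()` exports BED (0-based half-open).
#'
#' @param path file path.
#' @param annotation an [rdna_annotation()].
#' @return `read_annotation()` returns an [rdna_annotation()]; the writers
#'   return `path` invisibly.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  rdna_annotation(df)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "rdna_annotation"))
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotation
#' @param seqname chromosome/reference name to write in the BED file.
#' @export
write_annotation_bed <- function(annotation, path, seqname = "rDNA") {
  stopifnot(inherits(annotation, "rdna_annotation"))
  gr <- GenomicRanges::GRanges(
    seqname,
    IRanges::IRanges(start = annotation$start, end = annotation$end),
    name = annotation$name
  )
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Hybridization probe catalog
#'
#' Describes the single-stranded probes used for slot-blot quantification of
#' nascent transcripts. Each probe targets either a region of the annotated
#' unit or an external locus, and carries a role: `polI_signal` for probes
#' reporting Pol I nascent RNA, `control_5S` for the two probes covering the
#' Pol III 5S rRNA used as the normalization control, and `background_IGS2`
#' for the intergenic-spacer negative control. Exactly two `control_5S`
#' probes and at least one `background_IGS2` probe are required.
#'
#' @param probes data.frame with columns `name`, `target_region` (a region
#'   label or `"external"`), and `role`.
#' @return an object of class `probe_catalog` (a validated data.frame).
#' @export
probe_catalog <- function(probes) {
  stopifnot(is.data.frame(probes),
            all(c("name", "target_region", "role") %in% names(probes)))
  probes <- data.frame(name = as.character(probes$name),
                       target_region = as.character(probes$target_region),
                       role = as.character(probes$role),
                       stringsAsFactors = FALSE)
  ok_roles <- c("polI_signal", "control_5S", "background_IGS2")
  if (!all(probes$role %in% ok_roles))
    stop("probe roles must be one of: ", paste(ok_roles, collapse = ", "))
  if (anyDuplicated(probes$name))
    stop("probe names must be unique")
  if (sum(probes$role == "control_5S") != 2L)
    stop("exactly two control_5S probes are required")
  if (sum(probes$role == "background_IGS2") < 1L)
    stop("at least one background_IGS2 probe is required")
  structure(probes, class = c("probe_catalog", "data.frame"))
}

#' Default slot-blot probe catalog
#'
#' Three 5'ETS probes, one 18S and one 25S probe, a 3'ETS probe
#' (all `polI_signal`), the two 5S probes used as the normalization control,
#' and the IGS2 background probe.
#'
#' @return a [probe_catalog()].
#' @export
default_probe_catalog <- function() {
  probe_catalog(data.frame(
    name = c("5'ETS-1", "5'ETS-2", "5'ETS-3", "18S.2", "25S.1", "3'ETS",
             "5S US", "5S DS", "IGS2"),
    target_region = c("5'ETS", "5'ETS", "5'ETS", "18S", "25S", "3'ETS",
                      "external", "external", "external"),
    role = c(rep("polI_signal", 6L), "control_5S", "control_5S",
             "background_IGS2")
  ))
}
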