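#' Default colorname palette for genotype de-identification
#'
#' A fixed, ordered list of 40 colour names used to pseudonymise genotype
#' identifiers.  The first 27 are the colornames appearing in the public
#' dataset; the remainder provide head-room for larger genotype panels.
#'
#' @return Character vector of colour names.
#' @export
colorname_palette <- function() {
  c("Pink", "Red", "Azure", "Charcoal", "Scarlet", "Indigo", "Purple",
    "White", "Opal", "Ebony", "Bronze", "Orange", "Amber", "Emerald",
    "Copper", "Yellow", "Teal", "Beige", "Green", "Violet", "Crimson",
    "Cyan", "Blue", "Gray", "Turquoise", "Brown", "Black",
    "Magenta", "Olive", "Maroon", "Navy", "Coral", "Ivory", "Lilac",
    "Sienna", "Mint", "Plum", "Gold", "Silver", "Salmon")
}

#' Build a genotype-to-colorname de-identification map
#'
#' Implements the first step of the two-step de-identification protocol:
#' each genotype identifier is assigned a unique colorname.  The
#' assignment is deterministic for a fixed seed: the palette is shuffled
#' with the given seed and zipped against the genotype identifiers sorted
#' lexicographically (C locale), so the result is auditable and
#' independent of input order.
#'
#' @param genotypes Character vector (treated as a set) of genotype
#'   identifiers.
#' @param palette Ordered candidate colornames; must be at least as long
#'   as the genotype set.
#' @param seed Integer seed controlling the palette shuffle.
#' @return A `leafhair_deid_map`: list with `pairs` (named character
#'   vector, genotype -> colorname), `seed`, `created` (ISO-8601 UTC).
#' @export
build_deid_map <- function(genotypes, palette = colorname_palette(), seed = 1L) {
  genotypes <- sort(unique(as.character(genotypes)), method = "radix")
  palette <- unique(as.character(palette))
  if (length(palette) < length(genotypes))
    stop(sprintf("palette too small: %d colornames for %d genotypes",
                 length(palette), length(genotypes)))
  shuffled <- withr::with_seed(as.integer(seed), sample(palette))
  pairs <- stats::setNames(shuffled[seq_along(genotypes)], genotypes)
  structure(list(pairs = pairs, seed = as.integer(seed),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
            class = "leafhair_deid_map")
}

#' @export
print.leafhair_deid_map <- function(x, ...) {
  cat(sprintf("<de-identification map: %d genotypes, seed %d, created %s>\n",
              length(x$pairs), x$seed, x$created))
  invisible(x)
}

#' Apply (or invert) a de-identification map on a manifest
#'
#' Replaces every genotype identifier in the manifest with its colorname.
#' Any columns beyond the manifest schema (free-text site notes,
#' geo-tags, timestamps carried in from a raw export) are dropped; all
#' schema fields other than `genotype` are unchanged.  Record count, leaf
#' grouping and score distribution are preserved exactly.
#'
#' Applying the map a second time fails, because colornames are not keys
#' of the map; applying `invert_deid_map(map)` recovers the original
#' genotype identifiers exactly.
#'
#' @param manifest A manifest (or data.frame with at least the manifest
#'   columns).
#' @param map A `leafhair_deid_map`.
#' @return The de-identified manifest.
#' @export
apply_deid_map <- function(manifest, map) {
  stopifnot(inherits(map, "leafhair_deid_map"))
  m <- as.data.frame(manifest)
  extra <- setdiff(names(m), manifest_columns())
  if (length(extra)) m[extra] <- NULL
  if (nrow(m) == 0L) return(as_manifest(m))
  unmapped <- setdiff(unique(m$genotype), names(map$pairs))
  if (length(unmapped))
    stop("genotype(s) not present in de-identification map: ",
         paste(sQuote(unmapped), collapse = ", "))
  m$genotype <- unname(map$pairs[m$genotype])
  as_manifest(m)
}

#' @rdname apply_deid_map
#' @export
invert_deid_map <- function(map) {
  stopifnot(inherits(map, "leafhair_deid_map"))
  inv <- map
  inv$pairs <- stats::setNames(names(map$pairs), unname(map$pairs))
  inv
}

#' Persist / load the de-identification master file
#'
#' The master map is written as a two-column CSV (`genotype,colorname`)
#' plus a JSON sidecar (`<path>.json`) recording the seed and creation
#' time.  As a guard mirroring the protocol's separation-of-storage rule,
#' writing the master map into the same directory as a de-identified
#' manifest is refused; full access-control separation is organisational
#' and out of scope.
#'
#' @param map A `leafhair_deid_map`.
#' @param path Output CSV path for the master file.
#' @param deidentified_dir Optional directory holding de-identified
#'   artifacts; if `normalizePath(dirname(path))` equals it, writing is
#'   refused.
#' @return `path`, invisibly.
#' @export
write_deid_map <- function(map, path, deidentified_dir = NULL) {
  stopifnot(inherits(map, "leafhair_deid_map"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(deidentified_dir) && dir.exists(deidentified_dir) &&
      normalizePath(dirname(path)) == normalizePath(deidentified_dir))
    stop("refusing to write the de-identification master file into the ",
         "same directory as de-identified outputs: ", deidentified_dir)
  utils::write.csv(data.frame(genotype = names(map$pairs),
                              colorname = unname(map$pairs)),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = map$seed, created = map$created),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_deid_map
#' @export
read_deid_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"))
  else list(seed = NA_integer_, created = NA_character_)
  structure(list(pairs = stats::setNames(df$colorname, df$genotype),
                 seed = as.integer(meta$seed), created = meta$created),
            class = "leafhair_deid_map")
}

# ---- container-level image metadata stripping --------------------------

#' Strip identifying metadata from an image file
#'
#' Removes metadata containers (EXIF, XMP, GPS, timestamps, comments)
#' from a PNG or JPEG file at the byte-container level, without decoding
#' or re-encoding pixel data — the compressed pixel stream is copied
#' verbatim, so pixel data is bit-identical.
#'
#' * PNG: only the chunks required to decode pixels are kept (`IHDR`,
#'   `PLTE`, `tRNS`, `IDAT`, `IEND`); all ancillary chunks (`tEXt`,
#'   `zTXt`, `iTXt`, `tIME`, `eXIf`, `pHYs`, ...) are dropped.
#' * JPEG: all marker segments are kept except `APP1`-`APP15` (EXIF/XMP
#'   live in `APP1`) and `COM`; the `APP0` JFIF header (no identifying
#'   content) is retained.
#'
#' @param image_path_in Input image file (PNG or JPEG, detected by
#'   signature).
#' @param image_path_out Output path.
#' @return `image_path_out`, invisibly.
#' @export
strip_image_metadata <- function(image_path_in, image_path_out) {
  raw <- readBin(image_path_in, "raw", file.info(image_path_in)$size)
  png_sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  out <- if (length(raw) >= 8 && identical(raw[1:8], png_sig)) {
    strip_png_chunks(raw)
  } else if (length(raw) >= 2 && raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xD8)) {
    strip_jpeg_segments(raw)
  } else {
    stop("not a PNG or JPEG file (bad signature): ", image_path_in)
  }
  dir.create(dirname(image_path_out), recursive = TRUE, showWarnings = FALSE)
  writeBin(out, image_path_out)
  invisible(image_path_out)
}

be32 <- function(raw4) sum(as.integer(raw4) * c(16777216, 65536, 256, 1))

strip_png_chunks <- function(raw) {
  keep_types <- c("IHDR", "PLTE", "tRNS", "IDAT", "IEND")
  out <- list(raw[1:8])
  pos <- 9L
  n <- length(raw)
  repeat {
    if (pos + 7L > n) stop("corrupt PNG: truncated chunk header")
    len <- be32(raw[pos:(pos + 3L)])
    type <- rawToChar(raw[(pos + 4L):(pos + 7L)])
    end <- pos + 11L + len             # last byte of the chunk (incl. CRC)
    if (end > n) stop("corrupt PNG: chunk '", type, "' overruns file")
    if (type %in% keep_types) out[[length(out) + 1L]] <- raw[pos:end]
    pos <- end + 1L
    if (type == "IEND") break
    if (pos > n) stop("corrupt PNG: missing IEND")
  }
  do.call(c, out)
}

strip_jpeg_segments <- function(raw) {
  n <- length(raw)
  out <- list(raw[1:2])  # SOI
  pos <- 3L
  repeat {
    if (pos + 1L > n) stop("corrupt JPEG: ran past end before SOS")
    if (raw[pos] != as.raw(0xFF)) stop("corrupt JPEG: expected marker at byte ", pos)
    marker <- as.integer(raw[pos + 1L])
    if (marker == 0xD9) {  # EOI with no scan data
      out[[length(out) + 1L]] <- raw[pos:(pos + 1L)]
      break
    }
    if (marker == 0xDA) {  # SOS: copy the rest (entropy-coded data + EOI)
      out[[length(out) + 1L]] <- raw[pos:n]
      break
    }
    standalone <- marker %in% c(0x01, 0xD0:0xD7)
    if (standalone) {
      out[[length(out) + 1L]] <- raw[pos:(pos + 1L)]
      pos <- pos + 2L
      next
    }
    if (pos + 3L > n) stop("corrupt JPEG: truncated segment length")
    len <- as.integer(raw[pos + 2L]) * 256L + as.integer(raw[pos + 3L])
    end <- pos + 1L + len
    if (end > n) stop("corrupt JPEG: segment overruns file")
    drop <- (marker >= 0xE1 && marker <= 0xEF) || marker == 0xFE
    if (!drop) out[[length(out) + 1L]] <- raw[pos:(end)]
    pos <- end + 1L
  }
  do.call(c, out)
}
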