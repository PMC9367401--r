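#' @title COCO-format dataset I/O
#' @description Reading and writing of datasets in COCO layout: an image
#'   directory of PNGs plus an `annotations.json` with `images`,
#'   `annotations` (bbox `[x, y, w, h]`, polygon `segmentation`,
#'   `category_id`, `iscrowd`) and `categories`. The train/val split is kept
#'   in a per-image `split` field.
#' @name coco
NULL

#' Write a dataset to disk in COCO layout
#' @param ds A `coco_dataset` (see [generate_dataset()]).
#' @param dir Output directory (created if needed); images go to
#'   `dir/images`, annotations to `dir/annotations.json`, the manifest to
#'   `dir/manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_coco <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (im in ds$images) {
    if (is.null(im$array)) next
    png::writePNG(im$array, file.path(dir, "images", im$file_name))
  }
  images <- lapply(ds$images, function(im) {
    list(id = im$id, file_name = im$file_name, height = im$height,
         width = im$width, split = im$split, class_id = im$class_id)
  })
  anns <- lapply(ds$annotations, function(a) {
    list(id = a$id, image_id = a$image_id, category_id = a$category_id,
         bbox = round(a$bbox, 2), segmentation = a$segmentation,
         area = a$area, visible_area = a$visible_area, iscrowd = a$iscrowd,
         split = a$split)
  })
  top <- list(images = images, annotations = anns,
              categories = ds$categories)
  jsonlite::write_json(top, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(ds$manifest)) {
    jsonlite::write_json(
      list(per_class = ds$manifest, totals = manifest_summary(ds$manifest),
           split_ratio = ds$split_ratio),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset from COCO layout on disk
#' @param dir Directory written by [write_coco()].
#' @param load_images Read the PNGs into memory (default TRUE).
#' @return A `coco_dataset`.
#' @export
read_coco <- function(dir, load_images = TRUE) {
  top <- jsonlite::read_json(file.path(dir, "annotations.json"))
  images <- lapply(top$images, function(im) {
    arr <- NULL
    if (load_images) {
      p <- file.path(dir, "images", im$file_name)
      if (file.exists(p)) {
        arr <- png::readPNG(p)
        if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
        if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
      }
    }
    list(id = im$id, file_name = im$file_name, height = im$height,
         width = im$width, split = im$split %||% "train",
         class_id = im$class_id %||% NA_integer_, array = arr)
  })
  anns <- lapply(top$annotations, function(a) {
    list(id = a$id, image_id = a$image_id, category_id = a$category_id,
         bbox = as.numeric(unlist(a$bbox)),
         segmentation = lapply(a$segmentation, function(s)
           as.numeric(unlist(s))),
         area = a$area, visible_area = a$visible_area %||% NA,
         iscrowd = a$iscrowd %||% 0L, split = a$split %||% "train")
  })
  structure(list(images = images, annotations = anns,
                 categories = top$categories, classes = NULL,
                 manifest = NULL), class = "coco_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ground-truth polygon of an annotation as a contour.
annotation_polygon <- function(a) {
  if (inherits(a$segmentation, "contour")) return(a$segmentation)
  coco_to_contour(a$segmentation[[1]])
}

annotation_bbox <- function(a) bbox_from_xywh(as.numeric(a$bbox))
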