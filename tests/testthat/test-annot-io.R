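write_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("label parsing handles boxes, polygons and malformed lines", {
  s <- read_labels(write_tmp("0 0.5 0.5 0.2 0.2"), kind = "box")
  expect_equal(nrow(s$boxes), 1)
  expect_equal(s$boxes$cx, 0.5)
  expect_identical(s$source, "ground-truth")

  p <- read_labels(write_tmp("0 0.1 0.1 0.9 0.1 0.5 0.9"), kind = "polygon")
  expect_equal(length(p$polygons), 1)
  expect_equal(nrow(p$polygons[[1]]$vertices), 3)

  expect_error(read_labels(write_tmp("0 0.5 0.5 0.2"), kind = "box"),
               "line 1")
  expect_error(read_labels(write_tmp(c("0 0.5 0.5 0.2 0.2",
                                       "0 0.1 0.1 1.5 0.1")), kind = "box"),
               "line 2")
  expect_error(read_labels(write_tmp("0 0.1 0.1 0.9 0.1"), kind = "polygon"),
               "line 1")

  # prediction dialect: trailing confidence
  pb <- read_labels(write_tmp("0 0.5 0.5 0.2 0.2 0.87"), kind = "box")
  expect_identical(pb$source, "prediction")
  expect_equal(pb$boxes$confidence, 0.87)
  pp <- read_labels(write_tmp("0 0.1 0.1 0.9 0.1 0.5 0.9 0.75"),
                    kind = "polygon")
  expect_identical(pp$source, "prediction")
  expect_equal(pp$polygons[[1]]$confidence, 0.75)
})

test_that("write/read round trips preserve records to 1e-6", {
  set.seed(21)
  boxes <- data.frame(class_id = sample(0:2, 50, TRUE),
                      cx = runif(50), cy = runif(50),
                      w = runif(50, 0.01, 0.3), h = runif(50, 0.01, 0.3),
                      confidence = runif(50))
  s <- annotation_set("img1", boxes = boxes, source = "prediction")
  f <- withr::local_tempfile(fileext = ".txt")
  write_labels(s, f, kind = "box")
  back <- read_labels(f, kind = "box")
  expect_identical(back$source, "prediction")
  for (col in c("cx", "cy", "w", "h", "confidence")) {
    expect_lt(max(abs(back$boxes[[col]] - boxes[[col]])), 1e-6)
  }
  # every prediction record carries the 6th field
  expect_true(all(lengths(strsplit(readLines(f), " ")) == 6))

  polys <- lapply(1:10, function(i) {
    polygon_outline(matrix(runif(8), ncol = 2), class_id = i %% 3)
  })
  sp <- annotation_set("img2", polygons = polys)
  fp <- withr::local_tempfile(fileext = ".txt")
  write_labels(sp, fp, kind = "polygon")
  backp <- read_labels(fp, kind = "polygon")
  for (i in 1:10) {
    expect_lt(max(abs(backp$polygons[[i]]$vertices - polys[[i]]$vertices)),
              1e-6)
    expect_equal(backp$polygons[[i]]$class_id, polys[[i]]$class_id)
  }

  # empty set -> empty file
  fe <- withr::local_tempfile(fileext = ".txt")
  write_labels(annotation_set("e"), fe, kind = "box")
  expect_equal(length(readLines(fe)), 0)
})

test_that("dataset splitting gives floor-sized partitions, remainder to train", {
  ids <- sprintf("im%03d", 1:185)
  plan <- split_dataset(ids, seed = 4)
  expect_equal(lengths(plan[c("train", "validation", "test")]),
               c(train = 149L, validation = 18L, test = 18L))
  expect_identical(plan, split_dataset(ids, seed = 4))
  expect_false(identical(plan$train, split_dataset(ids, seed = 5)$train))

  small <- split_dataset(sprintf("i%02d", 1:10), seed = 1)
  expect_equal(lengths(small[c("train", "validation", "test")]),
               c(train = 8L, validation = 1L, test = 1L))

  # partition property over seeds
  for (s in 1:5) {
    p <- split_dataset(ids, seed = s)
    all_ids <- c(p$train, p$validation, p$test)
    expect_equal(sort(all_ids), sort(ids))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  expect_error(split_dataset(ids, ratio = c(0.8, 0.1, 0.2)), "sum to 1")
  expect_error(split_dataset(c("a", "b")), "at least 3")
})

aug_fixture <- function() {
  pl <- small_plate()
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- export_annotations(pl, dir)
  boxes <- read_labels(paths[["box"]], kind = "box")
  polys <- read_labels(paths[["berry"]], kind = "polygon")
  list(plate = pl,
       set = annotation_set(pl$image_id, boxes = boxes$boxes,
                            polygons = polys$polygons))
}

test_that("flips and 90-degree rotations preserve annotations exactly", {
  fx <- aug_fixture()
  size <- dim(fx$plate$image)[1:2]

  # box-only set: reflection acts on the box corners directly
  box_set <- annotation_set(fx$set$image_id, boxes = fx$set$boxes)
  hf <- augment_one(fx$plate$image, box_set, "hflip")
  expect_equal(hf$set$boxes$cx, 1 - box_set$boxes$cx)
  expect_equal(hf$set$boxes$cy, box_set$boxes$cy)
  expect_equal(hf$set$boxes$w, box_set$boxes$w)
  # paired set: boxes are rebuilt as hulls of the flipped polygons
  hf2 <- augment_one(fx$plate$image, fx$set, "hflip")
  expect_equal(hf2$set$boxes$cx, 1 - fx$set$boxes$cx, tolerance = 1e-2)

  for (op_angle in list(list("vflip", NULL), list("rotate", 90),
                        list("rotate", 180), list("rotate", 270))) {
    tr <- augment_one(fx$plate$image, fx$set, op_angle[[1]], op_angle[[2]])
    for (i in seq_along(fx$set$polygons)) {
      a0 <- sum(rasterize_polygon(fx$set$polygons[[i]], size[2], size[1]))
      a1 <- sum(rasterize_polygon(tr$set$polygons[[i]], size[2], size[1]))
      expect_equal(a1, a0)
    }
  }
})

test_that("arbitrary rotations keep areas within discretization tolerance", {
  fx <- aug_fixture()
  size <- dim(fx$plate$image)[1:2]
  tr <- augment_one(fx$plate$image, fx$set, "rotate", 30)
  for (i in seq_along(fx$set$polygons)) {
    a0 <- sum(rasterize_polygon(fx$set$polygons[[i]], size[2], size[1]))
    a1 <- sum(rasterize_polygon(tr$set$polygons[[i]], size[2], size[1]))
    expect_lt(abs(a1 - a0) / a0, 0.03)
  }
  # vertices stay normalized
  for (p in tr$set$polygons) {
    expect_true(all(p$vertices >= 0 & p$vertices <= 1))
  }
})

test_that("photometric ops change pixels but not annotations", {
  fx <- aug_fixture()
  for (op in c("saturation", "brightness", "exposure")) {
    tr <- augment_one(fx$plate$image, fx$set, op, 0.8)
    expect_identical(tr$set$boxes, fx$set$boxes)
    expect_identical(lapply(tr$set$polygons, `[[`, "vertices"),
                     lapply(fx$set$polygons, `[[`, "vertices"))
    expect_false(identical(tr$image, fx$plate$image))
    expect_true(all(tr$image >= 0 & tr$image <= 255))
  }
})

test_that("randomized augmentation is seeded and rejects unknown ops", {
  fx <- aug_fixture()
  r1 <- augment(fx$plate$image, fx$set, ops = c("hflip", "rotate",
                                                "brightness"),
                n_copies = 3, seed = 9)
  r2 <- augment(fx$plate$image, fx$set, ops = c("hflip", "rotate",
                                                "brightness"),
                n_copies = 3, seed = 9)
  expect_equal(length(r1), 3)
  for (k in 1:3) {
    expect_identical(r1[[k]]$image, r2[[k]]$image)
    expect_match(r1[[k]]$set$image_id, sprintf("aug%d$", k))
  }
  expect_error(augment(fx$plate$image, fx$set, ops = "mosaic"),
               "unknown augmentation op")
})
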