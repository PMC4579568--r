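mk_parts <- function(x) data.frame(particle_id = sprintf("h%02d", seq_along(x)),
                                   mt_id = "mt1", axial_x_nm = x)

canon_pairs <- function(p1, p2) sort(paste(pmin(p1, p2), pmax(p1, p2)))

test_that("isolate applies the 40-nm pairing and exclusion rules", {
  res <- isolate(mk_parts(c(0, 30, 100)))
  expect_equal(nrow(res$pairs), 1)
  expect_equal(c(res$pairs$particle_id_1, res$pairs$particle_id_2),
               c("h01", "h02"))
  expect_equal(res$singles, "h03")

  res <- isolate(mk_parts(c(0, 30, 60)))
  expect_equal(nrow(res$pairs), 0)
  expect_length(res$singles, 0)

  res <- isolate(mk_parts(0))
  expect_equal(res$singles, "h01")
  expect_equal(nrow(res$pairs), 0)

  expect_error(isolate(data.frame(particle_id = c("a", "a"),
                                  axial_x_nm = c(0, 10))), "duplicated")
  expect_error(isolate(mk_parts(c(0, NA))), "finite")
})

test_that("isolate agrees with the brute-force oracle on random fields", {
  set.seed(401)
  for (i in 1:300) {
    n <- sample(1:12, 1)
    parts <- mk_parts(sort(runif(n, 0, 400)))
    got <- isolate(parts)
    want <- isolate_oracle(parts)
    got_pairs <- canon_pairs(got$pairs$particle_id_1, got$pairs$particle_id_2)
    want_pairs <- canon_pairs(vapply(want$pairs, `[`, character(1), 1),
                              vapply(want$pairs, `[`, character(1), 2))
    expect_identical(got_pairs, want_pairs)
    expect_identical(sort(got$singles), sort(want$singles))
  }
})

test_that("normalized_pixel_sum is additive and offset-invariant", {
  geom <- motor_geometry()
  ip <- image_params()
  one <- data.frame(axial_x_nm = 40, ring_height_nm = 14, n_copies = 1)
  two <- data.frame(axial_x_nm = 40, ring_height_nm = 14, n_copies = 2)
  img1 <- render_micrograph(one, geom, ip)
  img2 <- render_micrograph(two, geom, ip)
  proi <- c(20L, 0L, 40L, 40L)   # around the ring
  mroi <- c(0L, 49L, 96L, 12L)   # the MT band
  broi <- c(70L, 0L, 20L, 30L)   # empty ice
  r1 <- normalized_pixel_sum(img1, proi, mroi, broi)
  r2 <- normalized_pixel_sum(img2, proi, mroi, broi)
  expect_equal(r2 / r1, 2.0, tolerance = 1e-12)
  # constant offset everywhere leaves the ratio unchanged
  r1c <- normalized_pixel_sum(img1 + 3.7, proi, mroi, broi)
  expect_equal(r1c, r1, tolerance = 1e-9)
  expect_error(normalized_pixel_sum(img1, proi, proi, broi), "overlap")
  expect_error(normalized_pixel_sum(img1 * 0, proi, mroi, broi),
               "measurement error")
})

test_that("classify_head_count separates monomers from superposed dimers", {
  expect_equal(classify_head_count(2.0, 1.0), "superposed_dimer")
  expect_equal(classify_head_count(1.0, 1.0), "monomer")
  expect_equal(classify_head_count(1.5, 1.0), "superposed_dimer")  # inclusive
  expect_error(classify_head_count(1.0, 0), "input error")
})

test_that("assign_roles keys on stalkhead position, supporting crossed stalks", {
  m <- data.frame(particle_id = c("a", "b"), stalkhead_x = c(10, 18),
                  ring_x = c(2, 4))
  r <- assign_roles(m)
  expect_equal(r$leading$particle_id, "b")
  expect_false(r$crossed)

  crossed <- data.frame(particle_id = c("a", "b"), stalkhead_x = c(10, 18),
                        ring_x = c(6, 1))
  r <- assign_roles(crossed)
  expect_equal(r$leading$particle_id, "b")  # stalkhead leads, ring trails
  expect_true(r$crossed)

  tie <- data.frame(particle_id = c("b", "a"), stalkhead_x = c(10, 10),
                    ring_x = c(1, 2))
  r <- assign_roles(tie)
  expect_true(r$ambiguous)
  expect_equal(r$leading$particle_id, "a")  # lower id leads on a tie
})

test_that("negative ring separation occurs exactly for crossed stalks", {
  set.seed(402)
  for (i in 1:100) {
    m <- data.frame(particle_id = c("a", "b"),
                    stalkhead_x = runif(2, 0, 30), ring_x = runif(2, -10, 20))
    if (m$stalkhead_x[1] == m$stalkhead_x[2]) next
    r <- assign_roles(m)
    seps <- dimer_separations(r$leading, r$trailing)
    expect_gte(seps$stalkhead_separation, 0)
    expect_identical(seps$ring_separation < 0, r$crossed)
  }
})
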