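# Shared fixture builders; everything is generated in code at test time.

counts_tbl <- function(n_bl6, n_jf1, ...) {
  tibble::tibble(n_bl6 = n_bl6, n_jf1 = n_jf1, ...)
}

# A clean three-channel spot field with known truth for colocalization tests.
make_field <- function(n_guide = 2000, shift = c(0.4, -0.3), jitter = 0.2,
                       spurious = 1e-4, p_b = 0.3, p_j = 0.3, seed = 1) {
  gen_spot_field(spot_field_spec(
    image_extent = c(512, 512), n_guide = n_guide, chromatic_shift = shift,
    localization_jitter_sd = jitter, coloc_prob_bl6 = p_b,
    coloc_prob_jf1 = p_j, spurious_density = spurious, rng_seed = seed))
}

# Guide image plus two SNV channel images with a bimodal amplitude split.
make_foci_images <- function(n = 50, extent = c(512, 512), psf_sd = 2,
                             seed = 1, frac_bl6 = 0.5,
                             amp_major = 900, amp_minor = 300) {
  im <- gen_foci_image(n, extent = extent, psf_sd = psf_sd,
                       rng_seed = seed)
  is_b <- withr::with_seed(seed + 1, runif(n) < frac_bl6)
  amps_b <- ifelse(is_b, amp_major, amp_minor)
  amps_j <- ifelse(is_b, amp_minor, amp_major)
  list(guide = im$image, truth = im$truth,
       identity = ifelse(is_b, "BL6", "JF1"),
       bl6 = render_foci_image(im$truth, amps_b, extent = extent,
                               psf_sd = psf_sd, rng_seed = seed + 2),
       jf1 = render_foci_image(im$truth, amps_j, extent = extent,
                               psf_sd = psf_sd, rng_seed = seed + 3))
}
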