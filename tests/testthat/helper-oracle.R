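# Independent reference implementations used as oracles.

## PSNR / SSIM / NMSE via scikit-image (an implementation independent of
## this package), exchanged through CSV files.
skimageMetrics <- function(a, b) {
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  fo <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fa, fb, fo)))
  utils::write.table(a, fa, row.names = FALSE, col.names = FALSE, sep = ",")
  utils::write.table(b, fb, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage.metrics import peak_signal_noise_ratio as psnr\n",
    "from skimage.metrics import structural_similarity as ssim\n",
    "a = np.loadtxt('%s', delimiter=','); b = np.loadtxt('%s', delimiter=',')\n",
    "p = psnr(b, a, data_range=1.0)\n",
    "s = ssim(a, b, data_range=1.0, gaussian_weights=True, sigma=1.5,\n",
    "         use_sample_covariance=False, win_size=11)\n",
    "n = float(np.sum((a-b)**2)/np.sum(b**2))\n",
    "open('%s','w').write('%%.12g,%%.12g,%%.12g\\n' %% (p, s, n))\n"),
    fa, fb, fo)
  status <- system2("python", c("-c", shQuote(code)))
  if (status != 0) stop("python oracle failed")
  v <- as.numeric(strsplit(readLines(fo), ",")[[1]])
  list(psnr = v[1], ssim = v[2], nmseFrac = v[3])
}
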