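// Monte Carlo photon transport through a rod + scatter-foil phantom onto an
// analyzer crystal. Per photon: uniform transverse position at the intrinsic
// resolution, Gaussian scattering draw, Bernoulli absorption (foil material
// and rod chord), deterministic two-interface refraction, Bernoulli analyzer
// acceptance with p = R(theta + dtheta_R + dtheta_S), optional Gaussian PSF
// jitter before binning. Uses R's RNG so set.seed() gives bit-identical
// images.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List simulate_image_cpp(NumericMatrix sigma_s,     // ny x nx, urad, per pixel
                        NumericMatrix foil_trans,  // ny x nx, in (0,1]
                        NumericVector y_centers,   // mm, per row (descending)
                        double pixel_mm,
                        double intrinsic_mm,
                        int n_photons,             // per pixel
                        double theta,              // analyzer offset, urad
                        double sigma_rc,           // RC width, urad
                        NumericVector rod_radius,  // mm, per cylinder
                        NumericVector rod_center,  // mm
                        NumericVector rod_mu,      // 1/mm
                        NumericVector rod_delta,   // dimensionless
                        double defl_cap,           // urad
                        double psf_sigma_mm) {
  const int ny = sigma_s.nrow(), nx = sigma_s.ncol();
  const int nrod = rod_radius.size();
  int m = (int)std::lround(pixel_mm / intrinsic_mm);
  if (m < 1) m = 1;
  const double sub_mm = pixel_mm / m;
  const double inv2s2 = 1.0 / (2.0 * sigma_rc * sigma_rc);
  const bool psf = psf_sigma_mm > 0.0;

  // Geometry lookup tables over the intrinsic sub-grid of every row:
  // chord transmission and deflection (urad) through all cylinders.
  std::vector<double> surv(ny * m, 1.0), defl(ny * m, 0.0);
  std::vector<bool> row_geom(ny, false);
  for (int r = 0; r < ny; ++r) {
    const double y_top = y_centers[r] + pixel_mm / 2.0;
    for (int j = 0; j < m; ++j) {
      const double y = y_top - (j + 0.5) * sub_mm;
      double s = 1.0, d = 0.0;
      for (int k = 0; k < nrod; ++k) {
        const double yy = y - rod_center[k], R = rod_radius[k];
        if (std::fabs(yy) < R) {
          const double half = std::sqrt(R * R - yy * yy);
          s *= std::exp(-rod_mu[k] * 2.0 * half);
          d += 2.0 * rod_delta[k] * yy / half * 1e6; // rad -> urad
        }
      }
      if (d > defl_cap) d = defl_cap;
      if (d < -defl_cap) d = -defl_cap;
      surv[r * m + j] = s;
      defl[r * m + j] = d;
      if (s != 1.0 || d != 0.0) row_geom[r] = true;
    }
  }

  IntegerMatrix counts(ny, nx);
  IntegerMatrix shot(ny, nx); // photons aimed at each pixel (before PSF)
  RNGScope scope;
  const double p_bg = std::exp(-theta * theta * inv2s2);

  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      shot(r, c) = n_photons;
      const double ss = sigma_s(r, c);
      const double ft = foil_trans(r, c);
      const bool geom = row_geom[r];
      if (!geom && ss <= 0.0 && ft >= 1.0 && !psf) {
        // pure background pixel: exact aggregation of the Bernoulli draws
        counts(r, c) = (int)R::rbinom((double)n_photons, p_bg);
        continue;
      }
      int acc = 0;
      for (int p = 0; p < n_photons; ++p) {
        int j = 0;
        if (geom || psf) {
          j = (int)(unif_rand() * m);
          if (j >= m) j = m - 1;
        }
        if (ft < 1.0 && unif_rand() >= ft) continue; // absorbed in foil
        double ang = theta;
        if (ss > 0.0) ang += norm_rand() * ss;       // scattering draw
        if (geom) {
          const double s = surv[r * m + j];
          if (s < 1.0 && unif_rand() >= s) continue; // absorbed in rod
          ang += defl[r * m + j];                    // refraction
        }
        if (unif_rand() >= std::exp(-ang * ang * inv2s2)) continue;
        if (psf) {
          const double y_top = y_centers[r] + pixel_mm / 2.0;
          const double y = y_top - (j + 0.5) * sub_mm +
                           norm_rand() * psf_sigma_mm;
          const double y0 = y_centers[0] + pixel_mm / 2.0;
          const int rr = (int)std::floor((y0 - y) / pixel_mm);
          if (rr >= 0 && rr < ny) counts(rr, c) += 1;
        } else {
          ++acc;
        }
      }
      counts(r, c) += acc;
    }
  }
  return List::create(_["counts"] = counts, _["shot"] = shot);
}
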