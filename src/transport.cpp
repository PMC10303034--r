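// Analog photon Monte Carlo with kerma-approximation voxel scoring.
//
// Photons are emitted from a point source on the axis toward a uniform
// disk on the phantom entry surface, transported with exponential free
// paths through a homogeneous voxelized box, and interact by
// photoelectric absorption, Klein-Nishina (free-electron) incoherent
// scattering, or Thomson-angular coherent scattering. All locally
// transferred energy is deposited in the voxel of the interaction
// (kerma approximation: secondary-electron ranges at <= 220 kVp are
// well below the depth-bin size). Uses R's RNG, so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MEC2 = 510.99895;  // keV

// sample cos(theta) from the Klein-Nishina angular distribution at
// energy E by rejection against the forward maximum (value 2)
static inline double kn_cos(double E) {
  const double k = E / MEC2;
  for (;;) {
    double c = 2.0 * unif_rand() - 1.0;
    double eps = 1.0 / (1.0 + k * (1.0 - c));
    double f = eps * eps * (eps + 1.0 / eps - (1.0 - c * c));
    if (2.0 * unif_rand() <= f) return c;
  }
}

// sample cos(theta) from the Thomson angular form (1 + cos^2)/2
static inline double thomson_cos() {
  for (;;) {
    double c = 2.0 * unif_rand() - 1.0;
    if (unif_rand() <= 0.5 * (1.0 + c * c)) return c;
  }
}

// rotate unit vector (ux,uy,uz) by polar angle with cosine c and
// uniform azimuth
static inline void rotate_dir(double &ux, double &uy, double &uz, double c) {
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  double x, y, z;
  if (std::fabs(uz) > 0.999999) {
    // near the pole: local frame aligned with z
    x = s * cp; y = s * sp; z = c * (uz > 0 ? 1.0 : -1.0);
  } else {
    double r = std::sqrt(ux * ux + uy * uy);
    // t1 = normalized (u x z_hat), t2 = u x t1
    double t1x = uy / r, t1y = -ux / r;
    double t2x = uy * 0.0 - uz * t1y, t2y = uz * t1x - ux * 0.0,
           t2z = ux * t1y - uy * t1x;
    x = c * ux + s * (cp * t1x + sp * t2x);
    y = c * uy + s * (cp * t1y + sp * t2y);
    z = c * uz + s * (sp * t2z);
  }
  double n = std::sqrt(x * x + y * y + z * z);
  ux = x / n; uy = y / n; uz = z / n;
}

// [[Rcpp::export]]
List cpp_transport(NumericVector spec_energy, NumericVector spec_cdf,
                   double egrid_min, double egrid_step,
                   NumericVector mu_pe, NumericVector mu_ic,
                   NumericVector mu_co,
                   double half_x, double half_y, double depth,
                   int nx, int ny, int nz,
                   double ssd, double field_radius,
                   double n_histories, int n_batches, double cutoff,
                   bool k_fluor, NumericVector p_fluor,
                   NumericVector e_fluor) {
  const int nvox = nx * ny * nz;
  const int negrid = mu_pe.size();
  const double vx = 2.0 * half_x / nx, vy = 2.0 * half_y / ny,
               vz = depth / nz;
  const long per_batch = (long)(n_histories / n_batches + 0.5);

  NumericVector deposit((R_xlen_t)nvox * n_batches);
  NumericVector emitted(n_batches), escaped(n_batches), deposited(n_batches);
  const int nspec = spec_energy.size();

  RNGScope scope;
  for (int b = 0; b < n_batches; ++b) {
    double *dep = deposit.begin() + (R_xlen_t)nvox * b;
    for (long h = 0; h < per_batch; ++h) {
      // source: energy from the spectrum CDF, direction to a uniform
      // point on the entry disk
      double u = unif_rand();
      int lo = 0, hi = nspec - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid;
      }
      double E = spec_energy[lo];
      double rr = field_radius * std::sqrt(unif_rand());
      double ph = 2.0 * M_PI * unif_rand();
      double px = rr * std::cos(ph), py = rr * std::sin(ph), pz = 0.0;
      double nrm = std::sqrt(px * px + py * py + ssd * ssd);
      double ux = px / nrm, uy = py / nrm, uz = ssd / nrm;

      emitted[b] += E;
      double edep_hist = 0.0;
      bool alive = true;
      while (alive) {
        int ie = (int)((E - egrid_min) / egrid_step + 0.5);
        if (ie < 0) ie = 0;
        if (ie >= negrid) ie = negrid - 1;
        double mpe = mu_pe[ie], mic = mu_ic[ie], mco = mu_co[ie];
        double mtot = mpe + mic + mco;
        double s = -std::log(unif_rand()) / mtot;
        px += s * ux; py += s * uy; pz += s * uz;
        if (px <= -half_x || px >= half_x || py <= -half_y ||
            py >= half_y || pz <= 0.0 || pz >= depth) {
          escaped[b] += E;
          break;
        }
        int ix = (int)((px + half_x) / vx);
        int iy = (int)((py + half_y) / vy);
        int iz = (int)(pz / vz);
        if (ix >= nx) ix = nx - 1;
        if (iy >= ny) iy = ny - 1;
        if (iz >= nz) iz = nz - 1;
        R_xlen_t vidx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);

        double chan = unif_rand() * mtot;
        if (chan < mpe) {
          // photoelectric: full local deposition, optionally with
          // K-fluorescence escape modelling
          if (k_fluor && p_fluor[ie] > 0.0 && unif_rand() < p_fluor[ie]) {
            double ef = e_fluor[ie];
            dep[vidx] += E - ef; edep_hist += E - ef;
            E = ef;
            double c = 2.0 * unif_rand() - 1.0;  // isotropic re-emission
            double sphi = 2.0 * M_PI * unif_rand();
            double st = std::sqrt(1.0 - c * c);
            ux = st * std::cos(sphi); uy = st * std::sin(sphi); uz = c;
            continue;
          }
          dep[vidx] += E; edep_hist += E;
          alive = false;
        } else if (chan < mpe + mic) {
          // incoherent: Klein-Nishina kinematics, deposit E - E'
          double c = kn_cos(E);
          double eps = 1.0 / (1.0 + (E / MEC2) * (1.0 - c));
          double Enew = E * eps;
          dep[vidx] += E - Enew; edep_hist += E - Enew;
          E = Enew;
          rotate_dir(ux, uy, uz, c);
          if (E < cutoff) {  // below cutoff: deposit remainder locally
            dep[vidx] += E; edep_hist += E;
            alive = false;
          }
        } else {
          // coherent: deflection only, no energy transfer
          rotate_dir(ux, uy, uz, thomson_cos());
        }
      }
      deposited[b] += edep_hist;
    }
  }
  return List::create(_["deposit"] = deposit, _["emitted"] = emitted,
                      _["escaped"] = escaped, _["deposited"] = deposited);
}

// [[Rcpp::export]]
List cpp_kn_sample(double energy, int n) {
  NumericVector cth(n), esc(n);
  RNGScope scope;
  const double k = energy / MEC2;
  for (int i = 0; i < n; ++i) {
    double c = kn_cos(energy);
    cth[i] = c;
    esc[i] = energy / (1.0 + k * (1.0 - c));
  }
  return List::create(_["cos_theta"] = cth, _["energy"] = esc);
}

// [[Rcpp::export]]
NumericVector cpp_thomson_sample(int n) {
  NumericVector cth(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) cth[i] = thomson_cos();
  return cth;
}
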