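// Monte Carlo Compton/Rayleigh scatter transport through a laterally bounded
// slab stack, with next-event estimation onto a coarse detector grid.
//
// Units: mm, keV.  Attenuation tables are passed as linear coefficients
// (1/mm) on a fine uniform energy grid.  The R wrapper owns all random-seed
// handling; this kernel draws from R's RNG stream.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double MEC2 = 510.99895;        // electron rest energy, keV
static const double RE2_HALF = 0.5 * 2.8179403e-13 * 2.8179403e-13; // cm^2

struct MuTable {
  // columns: materials, rows: fine energy grid
  const double* data;
  int n_e, n_mat;
  double e0, de;
  double at(double E, int mat) const {
    double f = (E - e0) / de;
    if (f < 0) f = 0;
    int i = (int)f;
    if (i >= n_e - 1) { i = n_e - 2; f = n_e - 1; }
    double w = f - i;
    const double* col = data + (size_t)mat * n_e;
    return col[i] * (1 - w) + col[i + 1] * w;
  }
};

struct Slabs {
  std::vector<double> z0, z1; // per material layer (air excluded)
  std::vector<int> mat;
  double lat;                 // lateral half size of the stack
  double zmin, zmax;          // z extent of material layers
};

// Total Klein-Nishina cross-section per electron (cm^2).
static double kn_sigma(double E) {
  double k = E / MEC2;
  double t1 = (1 + k) / (k * k) * (2 * (1 + k) / (1 + 2 * k) - std::log(1 + 2 * k) / k);
  double t2 = std::log(1 + 2 * k) / (2 * k);
  double t3 = (1 + 3 * k) / ((1 + 2 * k) * (1 + 2 * k));
  return 2 * M_PI * 2 * RE2_HALF * (t1 + t2 - t3);
}

// Optical depth along ray p + t*u for t in [0, tmax] through the slab stack.
static double optical_depth(const Slabs& g, const MuTable& mu, double E,
                            const double p[3], const double u[3], double tmax) {
  double tau = 0;
  for (size_t i = 0; i < g.z0.size(); ++i) {
    double ta, tb;
    if (std::fabs(u[2]) < 1e-12) {
      if (p[2] < g.z0[i] || p[2] > g.z1[i]) continue;
      ta = 0; tb = tmax;
    } else {
      ta = (g.z0[i] - p[2]) / u[2];
      tb = (g.z1[i] - p[2]) / u[2];
      if (ta > tb) std::swap(ta, tb);
      ta = std::max(ta, 0.0); tb = std::min(tb, tmax);
      if (ta >= tb) continue;
    }
    // clip against lateral bounds |x|,|y| <= lat
    for (int ax = 0; ax < 2; ++ax) {
      if (std::fabs(u[ax]) < 1e-12) {
        if (std::fabs(p[ax]) > g.lat) { ta = tb; break; }
      } else {
        double c1 = (-g.lat - p[ax]) / u[ax];
        double c2 = (g.lat - p[ax]) / u[ax];
        if (c1 > c2) std::swap(c1, c2);
        ta = std::max(ta, c1); tb = std::min(tb, c2);
      }
    }
    if (ta < tb) tau += mu.at(E, g.mat[i]) * (tb - ta);
  }
  return tau;
}

// Sample a free-path collision along p + t*u within the slab stack.
// Returns true and sets t_coll and mat_coll if a collision occurs.
static bool sample_collision(const Slabs& g, const MuTable& mu, double E,
                             const double p[3], const double u[3],
                             double& t_coll, int& mat_coll) {
  // collect candidate segments per layer (they are z-disjoint)
  struct Seg { double ta, tb; int mat; };
  std::vector<Seg> segs;
  for (size_t i = 0; i < g.z0.size(); ++i) {
    double ta, tb;
    if (std::fabs(u[2]) < 1e-12) {
      if (p[2] < g.z0[i] || p[2] > g.z1[i]) continue;
      ta = 0; tb = 1e9;
    } else {
      ta = (g.z0[i] - p[2]) / u[2];
      tb = (g.z1[i] - p[2]) / u[2];
      if (ta > tb) std::swap(ta, tb);
      ta = std::max(ta, 1e-9);
      if (ta >= tb) continue;
    }
    bool dead = false;
    for (int ax = 0; ax < 2 && !dead; ++ax) {
      if (std::fabs(u[ax]) < 1e-12) {
        if (std::fabs(p[ax]) > g.lat) dead = true;
      } else {
        double c1 = (-g.lat - p[ax]) / u[ax];
        double c2 = (g.lat - p[ax]) / u[ax];
        if (c1 > c2) std::swap(c1, c2);
        ta = std::max(ta, c1); tb = std::min(tb, c2);
      }
    }
    if (!dead && ta < tb) segs.push_back({ta, tb, g.mat[i]});
  }
  if (segs.empty()) return false;
  std::sort(segs.begin(), segs.end(),
            [](const Seg& a, const Seg& b) { return a.ta < b.ta; });
  double target = -std::log(unif_rand());
  double acc = 0;
  for (const Seg& s : segs) {
    double m = mu.at(E, s.mat);
    double dtau = m * (s.tb - s.ta);
    if (acc + dtau >= target) {
      t_coll = s.ta + (target - acc) / m;
      mat_coll = s.mat;
      return true;
    }
    acc += dtau;
  }
  return false;
}

// Sample a Klein-Nishina scattering angle by rejection (bound f <= 2).
static double kn_sample_cos(double E) {
  double k = E / MEC2;
  for (;;) {
    double c = 2 * unif_rand() - 1;
    double kappa = 1 / (1 + k * (1 - c));
    double f = kappa * kappa * (kappa + 1 / kappa - (1 - c * c));
    if (2 * unif_rand() <= f) return c;
  }
}

// Rotate reference direction u by polar angle (cos_t) and uniform azimuth.
static void rotate_direction(double u[3], double cos_t) {
  double sin_t = std::sqrt(std::max(0.0, 1 - cos_t * cos_t));
  double phi = 2 * M_PI * unif_rand();
  double w[3];
  // build an orthonormal basis (a, b, u)
  double a[3], b[3];
  if (std::fabs(u[2]) < 0.99) { a[0] = -u[1]; a[1] = u[0]; a[2] = 0; }
  else { a[0] = 1; a[1] = 0; a[2] = 0; }
  double na = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
  // orthogonalize a against u
  double dot = (a[0]*u[0] + a[1]*u[1] + a[2]*u[2]);
  for (int i = 0; i < 3; ++i) a[i] -= dot * u[i];
  na = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
  for (int i = 0; i < 3; ++i) a[i] /= na;
  b[0] = u[1]*a[2] - u[2]*a[1];
  b[1] = u[2]*a[0] - u[0]*a[2];
  b[2] = u[0]*a[1] - u[1]*a[0];
  for (int i = 0; i < 3; ++i)
    w[i] = cos_t * u[i] + sin_t * (std::cos(phi) * a[i] + std::sin(phi) * b[i]);
  double nw = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
  for (int i = 0; i < 3; ++i) u[i] = w[i] / nw;
}

// [[Rcpp::export(name = ".mc_scatter_cpp")]]
NumericVector mc_scatter_cpp(int n_photons,
                             NumericVector spec_energy, NumericVector spec_prob,
                             double fluence_total, double det_half, double det_z,
                             NumericMatrix layer_z,   // nlayer x 2 (z0, z1)
                             IntegerVector layer_mat, // 0-based material index
                             double lateral_half,
                             NumericMatrix mu_tot, NumericMatrix mu_compton,
                             NumericMatrix mu_rayleigh,
                             double mu_e0, double mu_de,
                             NumericVector node_x,    // coarse node centers
                             double cell_area,
                             int e_bin_min, int n_ebins,
                             int max_order, bool rayleigh) {
  RNGScope scope;
  Slabs g;
  for (int i = 0; i < layer_z.nrow(); ++i) {
    g.z0.push_back(layer_z(i, 0));
    g.z1.push_back(layer_z(i, 1));
    g.mat.push_back(layer_mat[i]);
  }
  g.lat = lateral_half;

  MuTable Mtot{REAL(mu_tot), mu_tot.nrow(), mu_tot.ncol(), mu_e0, mu_de};
  MuTable Mcom{REAL(mu_compton), mu_compton.nrow(), mu_compton.ncol(), mu_e0, mu_de};
  MuTable Mray{REAL(mu_rayleigh), mu_rayleigh.nrow(), mu_rayleigh.ncol(), mu_e0, mu_de};

  int nn = node_x.size();
  NumericVector score(nn * nn * n_ebins); // fluence per mm^2, [x, y, Ebin]

  // cumulative spectrum for energy sampling
  std::vector<double> cum(spec_prob.size());
  double s = 0;
  for (int i = 0; i < spec_prob.size(); ++i) { s += spec_prob[i]; cum[i] = s; }
  for (double& c : cum) c /= s;

  double area_det = 4 * det_half * det_half;

  for (int ph = 0; ph < n_photons; ++ph) {
    // aim at a uniform point on the detector
    double xd = (2 * unif_rand() - 1) * det_half;
    double yd = (2 * unif_rand() - 1) * det_half;
    double norm = std::sqrt(xd * xd + yd * yd + det_z * det_z);
    double u[3] = {xd / norm, yd / norm, det_z / norm};
    double cos_t = det_z / norm;
    double w = fluence_total * area_det * cos_t * cos_t * cos_t / n_photons;
    double p[3] = {0, 0, 0};
    // sample energy
    double r = unif_rand();
    int ei = std::lower_bound(cum.begin(), cum.end(), r) - cum.begin();
    double E = spec_energy[std::min<int>(ei, spec_energy.size() - 1)];

    for (int order = 1; order <= max_order; ++order) {
      double t_coll; int mat;
      if (!sample_collision(g, Mtot, E, p, u, t_coll, mat)) break;
      for (int i = 0; i < 3; ++i) p[i] += t_coll * u[i];
      double mt = Mtot.at(E, mat);
      double mc = Mcom.at(E, mat);
      double mr = rayleigh ? Mray.at(E, mat) : 0.0;
      double surv = (mc + mr) / mt;      // implicit capture of photoelectric
      if (surv <= 0) break;
      w *= surv;
      bool is_compton = (!rayleigh) || (unif_rand() * (mc + mr) <= mc);
      double k = E / MEC2;
      double sig_kn = kn_sigma(E);

      // next-event estimation onto every coarse node
      for (int iy = 0; iy < nn; ++iy) {
        for (int ix = 0; ix < nn; ++ix) {
          double v[3] = {node_x[ix] - p[0], node_x[iy] - p[1], det_z - p[2]};
          double rr = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
          if (rr <= 0) continue;
          for (int i = 0; i < 3; ++i) v[i] /= rr;
          if (v[2] <= 0) continue;       // node behind the collision plane
          double mu_dir = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
          double Ep, pdf;
          if (is_compton) {
            double kappa = 1 / (1 + k * (1 - mu_dir));
            Ep = E * kappa;
            if (Ep < e_bin_min) continue;
            pdf = RE2_HALF * kappa * kappa *
              (kappa + 1 / kappa - (1 - mu_dir * mu_dir)) / sig_kn;
          } else {
            Ep = E;
            // Thomson angular shape (form-factor-free), normalized
            pdf = 3.0 / (16.0 * M_PI) * (1 + mu_dir * mu_dir);
          }
          double tau = optical_depth(g, Mtot, Ep, p, v, rr);
          if (tau > 30) continue;
          double contrib = w * pdf * (v[2] / (rr * rr)) * cell_area *
            std::exp(-tau);
          int eb = (int)std::lround(Ep) - e_bin_min;
          if (eb < 0) eb = 0;
          if (eb >= n_ebins) eb = n_ebins - 1;
          score[(size_t)eb * nn * nn + (size_t)iy * nn + ix] +=
            contrib / cell_area;
        }
      }

      // analog continuation
      double c;
      if (is_compton) {
        c = kn_sample_cos(E);
        E = E / (1 + k * (1 - c));
      } else {
        // Thomson: pdf prop to 1 + c^2; rejection against bound 2
        do { c = 2 * unif_rand() - 1; } while (2 * unif_rand() > 1 + c * c);
      }
      if (E < e_bin_min) break;
      rotate_direction(u, c);
    }
  }
  score.attr("dim") = IntegerVector::create(nn, nn, n_ebins);
  return score;
}

// [[Rcpp::export(name = ".kn_sample_cpp")]]
NumericMatrix kn_sample_cpp(double energy_kev, int n) {
  RNGScope scope;
  NumericMatrix out(n, 2);
  double k = energy_kev / MEC2;
  for (int i = 0; i < n; ++i) {
    double c = kn_sample_cos(energy_kev);
    out(i, 0) = c;
    out(i, 1) = energy_kev / (1 + k * (1 - c));
  }
  colnames(out) = CharacterVector::create("cos_theta", "energy_kev");
  return out;
}
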