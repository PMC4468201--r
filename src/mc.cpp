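// MCML-style Monte Carlo photon transport for layered turbid media.
//
// Geometry: photon launched at the origin travelling +z into layer 0; the
// ambient medium (probe face / air) sits above z = 0.  Layers are stacked in
// +z with the last layer semi-infinite unless a finite thickness is given.
// Exit records (radius, direction cosine in the ambient medium, residual
// weight, per-layer path length) are the substrate of the single-baseline
// scaling model: a baseline run with mu_a = 0 can be reweighted to any
// absorption level by exp(-mu_a * path) and rescaled in radius by the ratio
// of interaction coefficients.
//
// The RNG is std::mt19937_64 with an explicit 53-bit uniform conversion so
// that a given seed reproduces the same photon histories on any platform.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double runif01(std::mt19937_64 &gen) {
  // uniform in (0,1): never 0 (safe for log), never 1
  return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

struct Layer {
  double mua, mus, mut, g, n, z0, z1;
};

// Unpolarized Fresnel reflectance for |cos(theta_i)| = ci going n_i -> n_t.
// On transmission ct receives |cos(theta_t)|.
static inline double fresnel_R(double ni, double nt, double ci, double &ct) {
  if (ni == nt) { ct = ci; return 0.0; }
  if (ci > 0.9999999) { // normal incidence
    ct = 1.0;
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = ni / nt * si;
  if (st >= 1.0) { ct = 0.0; return 1.0; } // total internal reflection
  ct = std::sqrt(1.0 - st * st);
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List run_mc_cpp(NumericMatrix layers, double n_ambient, int n_photons,
                int seed, double w_min, double p_survive,
                double z_kill, double r_kill, double max_steps,
                double launch_radius) {
  const int nl = layers.nrow();
  std::vector<Layer> L(nl);
  double z = 0.0;
  for (int i = 0; i < nl; ++i) {
    L[i].mua = layers(i, 0);
    L[i].mus = layers(i, 1);
    L[i].g   = layers(i, 2);
    L[i].n   = layers(i, 3);
    double th = layers(i, 4);
    L[i].mut = L[i].mua + L[i].mus;
    L[i].z0 = z;
    L[i].z1 = R_FINITE(th) ? z + th : R_PosInf;
    z = L[i].z1;
    if (L[i].mut <= 0.0) stop("layer %d has mu_t <= 0", i + 1);
  }

  std::mt19937_64 gen(static_cast<uint64_t>(seed));

  // ledger (all in units of launched weight; launched total = n_photons)
  double specular = 0.0, diffuse = 0.0, transmitted = 0.0, absorbed = 0.0;
  double lost = 0.0, roulette_loss = 0.0, roulette_gain = 0.0;

  std::vector<double> rec_r, rec_x, rec_y, rec_cost, rec_w, rec_path;
  rec_r.reserve(n_photons / 2);
  rec_path.reserve(static_cast<size_t>(n_photons / 2) * nl);

  const double r_kill2 = r_kill * r_kill;
  // specular reflection at launch (normal incidence, ambient -> layer 0)
  double rsp = 0.0;
  {
    double r = (n_ambient - L[0].n) / (n_ambient + L[0].n);
    rsp = r * r;
  }

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, zz = 0.0;
    if (launch_radius > 0.0) { // uniform over a source disc (direct-geometry mode)
      double rr = launch_radius * std::sqrt(runif01(gen));
      double ph = 2.0 * M_PI * runif01(gen);
      x = rr * std::cos(ph);
      y = rr * std::sin(ph);
    }
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int l = 0;
    double w = 1.0 - rsp;
    specular += rsp;
    std::vector<double> path(nl, 0.0);
    double sleft = 0.0;
    double steps = 0.0;
    bool alive = true;

    while (alive) {
      if (sleft <= 0.0) sleft = -std::log(runif01(gen));
      double step = sleft / L[l].mut;

      // distance to the layer boundary along the current direction
      double db = R_PosInf;
      int dir = 0;
      if (uz > 0.0 && R_FINITE(L[l].z1)) { db = (L[l].z1 - zz) / uz; dir = 1; }
      else if (uz < 0.0) { db = (L[l].z0 - zz) / uz; dir = -1; }
      if (db < 0.0) db = 0.0;

      if (dir != 0 && db <= step) {
        // partial hop to the boundary
        x += ux * db; y += uy * db; zz += uz * db;
        path[l] += db;
        sleft -= db * L[l].mut;
        int lnew = l + dir;
        double nnext = (lnew < 0 || lnew >= nl) ? n_ambient : L[lnew].n;
        double ci = std::fabs(uz), ct;
        double R = fresnel_R(L[l].n, nnext, ci, ct);
        if (runif01(gen) < R) {
          uz = -uz; // internal reflection
          zz = (dir == 1) ? L[l].z1 : L[l].z0;
        } else if (lnew < 0) {
          // exits the top surface into the ambient medium
          diffuse += w;
          rec_r.push_back(std::sqrt(x * x + y * y));
          rec_x.push_back(x);
          rec_y.push_back(y);
          rec_cost.push_back(ct);
          rec_w.push_back(w);
          for (int k = 0; k < nl; ++k) rec_path.push_back(path[k]);
          alive = false;
        } else if (lnew >= nl) {
          transmitted += w;
          alive = false;
        } else {
          // refraction into the next layer
          double f = L[l].n / nnext;
          ux *= f; uy *= f;
          uz = (uz > 0.0) ? ct : -ct;
          l = lnew;
          zz = (dir == 1) ? L[l].z0 : L[l].z1;
        }
        continue;
      }

      // full hop
      x += ux * step; y += uy * step; zz += uz * step;
      path[l] += step;
      sleft = 0.0;
      steps += 1.0;

      if (zz > z_kill || x * x + y * y > r_kill2 || steps > max_steps) {
        lost += w;
        alive = false;
        continue;
      }

      // drop
      if (L[l].mua > 0.0) {
        double dw = w * L[l].mua / L[l].mut;
        absorbed += dw;
        w -= dw;
      }

      // spin: Henyey-Greenstein
      double g = L[l].g;
      double cth;
      if (std::fabs(g) < 1e-8) {
        cth = 2.0 * runif01(gen) - 1.0;
      } else {
        double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * runif01(gen));
        cth = (1.0 + g * g - t * t) / (2.0 * g);
        if (cth > 1.0) cth = 1.0; else if (cth < -1.0) cth = -1.0;
      }
      double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
      double phi = 2.0 * M_PI * runif01(gen);
      double cphi = std::cos(phi), sphi = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sth * cphi;
        uy = sth * sphi;
        uz = (uz >= 0.0) ? cth : -cth;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double uxn = sth * (ux * uz * cphi - uy * sphi) / den + ux * cth;
        double uyn = sth * (uy * uz * cphi + ux * sphi) / den + uy * cth;
        double uzn = -sth * cphi * den + uz * cth;
        ux = uxn; uy = uyn; uz = uzn;
      }

      // Russian roulette
      if (w < w_min) {
        if (runif01(gen) < p_survive) {
          roulette_gain += w * (1.0 / p_survive) - w;
          w /= p_survive;
        } else {
          roulette_loss += w;
          alive = false;
        }
      }
    }
  }

  const size_t nr = rec_r.size();
  NumericMatrix pathm(nr, nl);
  for (size_t i = 0; i < nr; ++i)
    for (int k = 0; k < nl; ++k) pathm(i, k) = rec_path[i * nl + k];

  return List::create(
    _["radius"] = NumericVector(rec_r.begin(), rec_r.end()),
    _["x"] = NumericVector(rec_x.begin(), rec_x.end()),
    _["y"] = NumericVector(rec_y.begin(), rec_y.end()),
    _["cos_exit"] = NumericVector(rec_cost.begin(), rec_cost.end()),
    _["weight"] = NumericVector(rec_w.begin(), rec_w.end()),
    _["path"] = pathm,
    _["ledger"] = NumericVector::create(
      _["specular"] = specular, _["diffuse"] = diffuse,
      _["transmitted"] = transmitted, _["absorbed"] = absorbed,
      _["lost"] = lost, _["roulette_loss"] = roulette_loss,
      _["roulette_gain"] = roulette_gain));
}

// Histogram of scaled exit radii with per-record absorption reweighting.
// Column j of the result holds, for absorption mua[j], the total weight
// w * exp(-mua[j] * pathlen * rscale) landing in each radial bin of width dr
// after the exit radius is rescaled by rscale.
// [[Rcpp::export]]
NumericMatrix scaled_bin_weights_cpp(NumericVector radius, NumericVector pathlen,
                                     NumericVector weight, double rscale,
                                     NumericVector mua, double dr, int nbins) {
  const int n = radius.size(), m = mua.size();
  NumericMatrix out(nbins, m);
  for (int i = 0; i < n; ++i) {
    double r = radius[i] * rscale;
    int b = static_cast<int>(r / dr);
    if (b < 0 || b >= nbins) continue;
    double Ls = pathlen[i] * rscale;
    double w = weight[i];
    for (int j = 0; j < m; ++j) out(b, j) += w * std::exp(-mua[j] * Ls);
  }
  return out;
}
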