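// Semianalytic Monte Carlo engine for triple-FOV oceanic HSRL returns.
//
// Photons are traced through a plane-parallel stack of water layers with
// scattering free paths sampled at rate b and continuous absorption
// weighting exp(-a * path). At every collision a local (next-event)
// estimator adds, per channel, the expected flux scattered into the receiver
// aperture times the direct return transmission exp(-tau_c) along the slant
// path. Channel acceptance is by the field angle of the collision point
// within each FOV cone. The ideal iodine filter separates channels by the
// photon frequency: a photon is Brillouin-shifted (passes the molecular
// filter) as soon as its history contains at least one molecular scattering,
// and particulate scatterings never unshift it. Molecular channels therefore
// accumulate the molecular part of every local scattering plus the
// particulate part for already-shifted photons; the combined channel
// accumulates both parts unconditionally.
//
// Two variance problems specific to backscatter lidar are handled:
//
// 1. The Fournier-Forand phase function is singular in the forward
//    direction, making the point estimator p(theta)*dOmega infinite-variance
//    for photons ascending nearly along the receiver axis. For scattering
//    angles within 20 aperture radii the estimator integrates the phase
//    function exactly over the aperture cone (closed-form CDF for the fully
//    covered inner region plus a 16-point log-Gauss wedge quadrature).
//
// 2. Return-leg multiple scattering is carried by paths that turn around
//    once (probability ~ BF + b_w/2b per collision, often ~1e-3) and then
//    forward-scatter toward the receiver; natural sampling of these paths is
//    hopelessly rare. Each trunk collision therefore splits the photon: the
//    trunk continues with a forward-hemisphere-conditional direction and
//    weight * (1 - P_B), while a backward branch of weight * P_B is pushed
//    onto a stack (roulette-thinned at birth against a reference weight) and
//    subsequently performs an ordinary unsplit walk. This decomposes every
//    path uniquely by its first backward deflection and is unbiased. The
//    branch direction is drawn from a defensive 50/50 mixture of the natural
//    backward-conditional phase and a receiver-aimed cap whose polar angle
//    follows the Fournier-Forand density (so that the subsequent estimator
//    spike p_FF(theta_sc) is cancelled by the importance weight), with the
//    exact mixture density divided out.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct FFLayer {
  double K, v, d180, pow_d180_v, bcoef, cterm, bf, fcap;
  // log-log interpolation tables of the phase density and its cumulative,
  // built once per layer from the closed forms (the estimator evaluates the
  // phase thousands of times per photon)
  std::vector<double> logpdf, cdf;
};

constexpr int TAB_N = 768;
constexpr double TAB_L0 = -27.6310211159285482;  // log(1e-12)
// log(pi) = 1.1447298858494002
constexpr double TAB_DL = (1.1447298858494002 - TAB_L0) / (TAB_N - 1);

inline double ff_pdf(double theta, const FFLayer &p) {
  double u = std::sin(0.5 * theta);
  u *= u;
  if (u < 1e-300) u = 1e-300;
  double d = u / p.K;
  double dv = std::pow(d, p.v);
  double main = (p.v * (1.0 - d) - (1.0 - dv) +
                 (d * (1.0 - dv) - p.v * (1.0 - d)) / u) /
                (4.0 * M_PI * (1.0 - d) * (1.0 - d) * dv);
  double c = std::cos(theta);
  return main + p.bcoef * (3.0 * c * c - 1.0);
}

inline double ff_cdf(double theta, const FFLayer &p) {
  double u = std::sin(0.5 * theta);
  u *= u;
  if (u <= 0.0) return 0.0;
  double d = u / p.K;
  double dv = std::pow(d, p.v);
  double main = (1.0 - dv * d - u * (1.0 - dv)) / ((1.0 - d) * dv);
  double bterm = p.cterm * (2.0 * u - 6.0 * u * u + 4.0 * u * u * u);
  double f = main + bterm;
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

inline double ff_pdf_tab(double theta, const FFLayer &p) {
  double lt = std::log(std::max(theta, 1e-12));
  double pos = (lt - TAB_L0) / TAB_DL;
  if (pos < 0.0) pos = 0.0;
  int i0 = (int)pos;
  if (i0 > TAB_N - 2) i0 = TAB_N - 2;
  double fr = pos - i0;
  return std::exp(p.logpdf[i0] * (1.0 - fr) + p.logpdf[i0 + 1] * fr);
}

inline double ff_cdf_tab(double theta, const FFLayer &p) {
  double lt = std::log(std::max(theta, 1e-12));
  double pos = (lt - TAB_L0) / TAB_DL;
  if (pos < 0.0) pos = 0.0;
  int i0 = (int)pos;
  if (i0 > TAB_N - 2) i0 = TAB_N - 2;
  double fr = pos - i0;
  return p.cdf[i0] * (1.0 - fr) + p.cdf[i0 + 1] * fr;
}

inline double mol_pdf(double theta, double f) {
  double c = std::cos(theta);
  return (1.0 + f * c * c) / (4.0 * M_PI * (1.0 + f / 3.0));
}

inline double mol_cdf(double theta, double f) {
  double mu = std::cos(theta);
  return ((1.0 - mu) + f * (1.0 - mu * mu * mu) / 3.0) /
         (2.0 * (1.0 + f / 3.0));
}

// 16-point Gauss-Legendre nodes/weights on [-1, 1]
static const double GLX[16] = {
  -0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
  -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
  -0.2816035507792589, -0.0950125098376374,  0.0950125098376374,
   0.2816035507792589,  0.4580167776572274,  0.6178762444026438,
   0.7554044083550030,  0.8656312023878318,  0.9445750230732326,
   0.9894009349916499 };
static const double GLW[16] = {
   0.0271524594117541,  0.0622535239386479,  0.0951585116824928,
   0.1246289712555339,  0.1495959888165767,  0.1691565193950025,
   0.1826034150449236,  0.1894506104550685,  0.1894506104550685,
   0.1826034150449236,  0.1691565193950025,  0.1495959888165767,
   0.1246289712555339,  0.0951585116824928,  0.0622535239386479,
   0.0271524594117541 };

// Integral of a phase function over a circular aperture cone of half-angle
// alpha whose axis makes angle theta_sc with the photon direction.
template <typename PDF, typename CDF>
double cone_integral(double theta_sc, double alpha, double omega,
                     PDF pdf, CDF cdf) {
  if (theta_sc > 20.0 * alpha) return pdf(theta_sc) * omega;
  if (theta_sc < 1e-9) return cdf(alpha);
  double lo = std::fabs(theta_sc - alpha);
  double hi = theta_sc + alpha;
  if (hi > M_PI) hi = M_PI;
  double base = (theta_sc < alpha) ? cdf(std::max(lo, 1e-12)) : 0.0;
  double tlo = std::log(std::max(lo, 1e-12));
  double thi = std::log(hi);
  double halfw = 0.5 * (thi - tlo), mid = 0.5 * (thi + tlo);
  double ca = std::cos(alpha), cs = std::cos(theta_sc),
         ss = std::sin(theta_sc);
  double sum = 0.0;
  for (int i = 0; i < 16; ++i) {
    double th = std::exp(mid + halfw * GLX[i]);
    double st = std::sin(th);
    double denom = st * ss;
    double cphi = (denom > 1e-300)
      ? (ca - std::cos(th) * cs) / denom
      : ((std::cos(th) * cs < ca) ? 1.0 : -1.0);
    if (cphi > 1.0) cphi = 1.0;
    if (cphi < -1.0) cphi = -1.0;
    double phimax = std::acos(cphi);
    sum += GLW[i] * pdf(th) * 2.0 * phimax * st * th;
  }
  return base + halfw * sum;
}

struct PState {
  double x, y, z, ux, uy, uz, w, L;
  bool trunk;
  bool shifted;  // history contains a molecular (Brillouin) scattering
};

inline void rotate_direction(double &ux, double &uy, double &uz,
                             double theta, double phi) {
  const double st = std::sin(theta), ct = std::cos(theta);
  const double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.999999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * ((uz >= 0.0) ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    const double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    const double nz = -st * cp * den + uz * ct;
    const double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix mc_trace(int n_photons, int nbatch, double dz, int nbin,
                       double H, double rr, NumericVector theta_half,
                       NumericVector a, NumericVector b, NumericVector bp,
                       double bw, double depol_f,
                       NumericVector ffK, NumericVector ffv,
                       NumericVector ffbcoef,
                       NumericMatrix tab_fwd_logtheta,
                       NumericMatrix tab_bwd_theta,
                       NumericVector tabF90, IntegerVector tab_idx,
                       double wmin) {
  const double depth_max = nbin * dz;
  const double th_n = theta_half[0], th_m = theta_half[1],
               th_w = theta_half[2];
  const int nfwd = tab_fwd_logtheta.nrow(), nbwd = tab_bwd_theta.nrow();
  const double pb_ref = 1e-3;   // branch-spawn probability reference
  const double p_surv = 0.65;   // forced roulette survival for branch walks

  std::vector<FFLayer> lay(nbin);
  for (int i = 0; i < nbin; ++i) {
    FFLayer p;
    p.K = ffK[i];
    p.v = ffv[i];
    p.d180 = 1.0 / p.K;
    p.pow_d180_v = std::pow(p.d180, p.v);
    p.bcoef = ffbcoef[i];
    p.cterm = (1.0 - p.pow_d180_v) / (4.0 * (p.d180 - 1.0) * p.pow_d180_v);
    p.bf = 1.0 - ff_cdf(M_PI / 2.0, p);
    p.fcap = ff_cdf(0.7, p);  // FF fraction within the aiming cap
    p.logpdf.resize(TAB_N);
    p.cdf.resize(TAB_N);
    for (int j = 0; j < TAB_N; ++j) {
      double th = std::exp(TAB_L0 + j * TAB_DL);
      if (th > M_PI) th = M_PI;
      p.logpdf[j] = std::log(std::max(ff_pdf(th, p), 1e-300));
      p.cdf[j] = ff_cdf(th, p);
    }
    lay[i] = p;
  }
  // cumulative vertical extinction at layer edges
  std::vector<double> cumc(nbin + 1, 0.0);
  for (int i = 0; i < nbin; ++i) cumc[i + 1] = cumc[i] + (a[i] + b[i]) * dz;

  NumericMatrix out(nbin * 4, nbatch);
  RNGScope scope;
  std::vector<PState> stack;

  // sample a particulate deflection from the inverse-CDF tables;
  // hemi: 0 = unconditional, 1 = forward-conditional, 2 = backward-conditional
  auto sample_ff = [&](int li, int hemi) -> double {
    const int t = tab_idx[li];
    const double F90 = tabF90[t];
    double U = unif_rand();
    bool forward;
    if (hemi == 1) forward = true;
    else if (hemi == 2) forward = false;
    else { forward = (U < F90); if (forward) U /= F90; else U = (U - F90) / (1.0 - F90); }
    if (forward) {
      double pos = U * (nfwd - 1);
      int i0 = (int)pos;
      if (i0 > nfwd - 2) i0 = nfwd - 2;
      double fr = pos - i0;
      return std::exp(tab_fwd_logtheta(i0, t) * (1.0 - fr) +
                      tab_fwd_logtheta(i0 + 1, t) * fr);
    }
    double pos = U * (nbwd - 1);
    int i0 = (int)pos;
    if (i0 > nbwd - 2) i0 = nbwd - 2;
    double fr = pos - i0;
    return tab_bwd_theta(i0, t) * (1.0 - fr) + tab_bwd_theta(i0 + 1, t) * fr;
  };

  auto sample_mol = [&](int hemi) -> double {
    double mu;
    do {
      mu = unif_rand();
      if (hemi == 0) mu = 2.0 * mu - 1.0;        // unconditional
      else if (hemi == 2) mu = -mu;              // backward
    } while (unif_rand() * (1.0 + depol_f) > 1.0 + depol_f * mu * mu);
    return std::acos(mu);
  };

  for (int ph = 0; ph < n_photons; ++ph) {
    const int batch = (int)(((long long)ph) * nbatch / n_photons);
    stack.clear();
    stack.push_back(
      PState{0.0, 0.0, 0.0, 0.0, 0.0, 1.0, 1.0, 0.0, true, false});
    int nev = 0;

    while (!stack.empty() && nev < 200000) {
      PState st = stack.back();
      stack.pop_back();
      bool alive = true;

      while (alive && nev < 200000) {
        // ---- flight ----
        double tau = -std::log(std::max(unif_rand(), 1e-300));
        double asum = 0.0;
        int li = 0;
        while (true) {
          li = (int)std::floor((st.z + ((st.uz >= 0.0) ? 1e-9 : -1e-9)) / dz);
          if (li < 0) li = 0;
          if (li > nbin - 1) li = nbin - 1;
          double bl = b[li];
          double s_b;
          if (st.uz > 1e-12) s_b = ((li + 1) * dz - st.z) / st.uz;
          else if (st.uz < -1e-12) s_b = (li * dz - st.z) / st.uz;
          else s_b = 1e30;
          double s_t = (bl > 0.0) ? tau / bl : 1e30;
          double s = std::min(s_b, s_t);
          st.x += st.ux * s; st.y += st.uy * s; st.z += st.uz * s;
          st.L += s;
          asum += a[li] * s;
          tau -= bl * s;
          if (st.z <= 0.0 || st.z >= depth_max || st.L > 1e6) {
            alive = false;
            break;
          }
          if (tau <= 1e-12) break;  // collision here
        }
        st.w *= std::exp(-asum);
        if (!alive) break;
        ++nev;

        // ---- local estimator ----
        const double zh = st.z + H;
        const double dist = std::sqrt(st.x * st.x + st.y * st.y + zh * zh);
        const double cospsi = zh / dist;
        const double psi = std::acos(std::min(cospsi, 1.0));
        const double bl = b[li];
        const FFLayer &P = lay[li];
        if (psi <= th_w) {
          const double rx = -st.x / dist, ry = -st.y / dist, rz = -zh / dist;
          double cth = st.ux * rx + st.uy * ry + st.uz * rz;
          if (cth > 1.0) cth = 1.0;
          if (cth < -1.0) cth = -1.0;
          const double theta_sc = std::acos(cth);
          const double alpha = rr / dist;
          const double omega = M_PI * rr * rr * cospsi / (dist * dist);
          // molecular phase is bounded and smooth: point estimator suffices
          const double q_m = (bw / bl) * mol_pdf(theta_sc, depol_f) * omega;
          double q_p = 0.0;
          if (bp[li] > 0.0) {
            q_p = (bp[li] / bl) *
              cone_integral(theta_sc, alpha, omega,
                            [&](double t) { return ff_pdf_tab(t, P); },
                            [&](double t) { return ff_cdf_tab(t, P); });
          }
          const double slant_w = dist * st.z / zh;
          const double tau_ret =
            (cumc[li] + (a[li] + b[li]) * (st.z - li * dz)) * dist / zh;
          const double zapp = 0.5 * (st.L + slant_w);
          const int bin = (int)(zapp / dz);
          if (bin >= 0 && bin < nbin) {
            const double T = std::exp(-tau_ret);
            const double cm = st.w * (q_m + (st.shifted ? q_p : 0.0)) * T;
            if (psi <= th_n) out(bin, batch) += cm;
            if (psi <= th_m) out(bin + nbin, batch) += cm;
            out(bin + 2 * nbin, batch) += cm;
            out(bin + 3 * nbin, batch) += st.w * (q_m + q_p) * T;
          }
        }

        // ---- scatter (with first-turnaround splitting on the trunk) ----
        const double pmolB = 0.5 * bw;
        const double ppartB = P.bf * bp[li];
        const double PB = (pmolB + ppartB) / bl;
        if (st.trunk) {
          // backward branch, roulette-thinned at birth, direction drawn from
          // a defensive mixture (natural backward phase | receiver-aimed cap)
          const double wB = st.w * PB;
          if (wB > 1e-12) {
            // weight-independent spawn probability: branch weights then scale
            // with the local signal level instead of being quantized, which
            // keeps deep-bin contributions finely grained
            const double p_push = std::min(1.0, PB / pb_ref);
            if (unif_rand() < p_push) {
              const double rxh = -st.x / dist, ryh = -st.y / dist,
                           rzh = -zh / dist;
              double dx, dy, dzv;
              if (unif_rand() < 0.5) {
                // cap: FF-distributed polar angle about the receiver line
                const int t = tab_idx[li];
                double Ucap = std::max(unif_rand(), 1e-12) * P.fcap;
                double pos = (Ucap / tabF90[t]) * (nfwd - 1);
                int i0 = (int)pos;
                if (i0 > nfwd - 2) i0 = nfwd - 2;
                double fr = pos - i0;
                double gam = std::exp(tab_fwd_logtheta(i0, t) * (1.0 - fr) +
                                      tab_fwd_logtheta(i0 + 1, t) * fr);
                dx = rxh; dy = ryh; dzv = rzh;
                rotate_direction(dx, dy, dzv, gam, 2.0 * M_PI * unif_rand());
              } else {
                const bool molp = unif_rand() < pmolB / (pmolB + ppartB);
                const double th_d = molp ? sample_mol(2) : sample_ff(li, 2);
                dx = st.ux; dy = st.uy; dzv = st.uz;
                rotate_direction(dx, dy, dzv, th_d, 2.0 * M_PI * unif_rand());
              }
              double cth_d = dx * st.ux + dy * st.uy + dzv * st.uz;
              if (cth_d < 0.0) {  // genuinely backward w.r.t. the trunk
                const double th_d = std::acos(std::max(cth_d, -1.0));
                const double pm = mol_pdf(th_d, depol_f);
                const double pf = (bp[li] > 0.0) ? ff_pdf_tab(th_d, P) : 0.0;
                const double fnat = (bw * pm + bp[li] * pf) / (bl * PB);
                double cgam = dx * rxh + dy * ryh + dzv * rzh;
                if (cgam > 1.0) cgam = 1.0;
                const double gam = std::acos(cgam);
                // density of the cap component (present regardless of b_p)
                const double udens = (gam < 0.7) ? ff_pdf_tab(gam, P) / P.fcap
                                                 : 0.0;
                const double gdens = 0.5 * (fnat + udens);
                if (fnat > 0.0 && gdens > 0.0) {
                  PState br = st;
                  br.trunk = false;
                  br.w = (wB / p_push) * fnat / gdens;
                  br.ux = dx; br.uy = dy; br.uz = dzv;
                  const double pmol_d = bw * pm / (bw * pm + bp[li] * pf);
                  if (unif_rand() < pmol_d) br.shifted = true;
                  stack.push_back(br);
                }
              }
            }
          }
          // trunk continues into the forward hemisphere
          st.w *= (1.0 - PB);
          const double pmolF = 0.5 * bw;
          const double ppartF = (1.0 - P.bf) * bp[li];
          const bool mol = unif_rand() < pmolF / (pmolF + ppartF);
          if (mol) st.shifted = true;
          const double theta = mol ? sample_mol(1) : sample_ff(li, 1);
          rotate_direction(st.ux, st.uy, st.uz, theta,
                           2.0 * M_PI * unif_rand());
        } else {
          // ordinary unsplit walk
          const bool mol = unif_rand() < bw / bl;
          if (mol) st.shifted = true;
          const double theta = mol ? sample_mol(0) : sample_ff(li, 0);
          rotate_direction(st.ux, st.uy, st.uz, theta,
                           2.0 * M_PI * unif_rand());
        }

        // ---- roulette ----
        if (!st.trunk) {
          // branch walks are kept short by forced roulette: later-order
          // return contributions are small, so most effort stays on the
          // first branch collisions
          if (unif_rand() < p_surv) st.w /= p_surv;
          else alive = false;
        }
        if (alive && st.w < wmin) {
          if (unif_rand() < 0.5) st.w *= 2.0;
          else alive = false;
        }
      }
    }
  }
  return out;
}
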