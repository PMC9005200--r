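// Random-walk transport kernel: layered tissue with optional ellipsoidal
// inclusion, analog / discrete / continuous absorption weighting,
// Henyey-Greenstein or bidirectional scattering, Fresnel boundary physics,
// Russian roulette. Exit records are returned to R where all exit-side
// detector tallies (live and database re-tallies) share one code path.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const double C_MM_NS = 299.792458;  // speed of light in vacuum [mm/ns]
const double NUDGE   = 1e-9;        // post-crossing advance [mm]

// Uniform (0,1) draws from a fully specified MT19937 stream; the raw 32-bit
// output is used directly so results are identical across platforms.
struct MtStream {
  std::mt19937 gen;
  explicit MtStream(uint32_t seed) : gen(seed) {}
  double operator()() {
    return (static_cast<double>(gen()) + 0.5) * (1.0 / 4294967296.0);
  }
};

struct Ops { double mua, mus, g, n; };

// Region indices: 0 = air above, 1..L = layers top-down, L+1 = air below,
// L+2 = ellipsoidal inclusion (when present).
struct Tissue {
  int L = 0;
  std::vector<double> zmin, zmax;
  std::vector<Ops> props;
  bool has_ell = false;
  double cx = 0, cy = 0, cz = 0, ax = 1, ay = 1, az = 1;
  int ell_layer = -1;
  int n_regions() const { return L + 2 + (has_ell ? 1 : 0); }
  int ell_region() const { return L + 2; }
};

Tissue parse_tissue(const List& tl) {
  Tissue T;
  NumericMatrix lay = tl["layers"];
  T.L = lay.nrow();
  T.props.resize(T.L + 2);
  T.props[0] = Ops{0.0, 0.0, 0.0, as<double>(tl["n_above"])};
  for (int i = 0; i < T.L; ++i) {
    T.zmin.push_back(lay(i, 0));
    T.zmax.push_back(lay(i, 1));
    T.props[i + 1] = Ops{lay(i, 2), lay(i, 3), lay(i, 4), lay(i, 5)};
  }
  T.props[T.L + 1] = Ops{0.0, 0.0, 0.0, as<double>(tl["n_below"])};
  if (tl.containsElementNamed("ellipsoid") && !Rf_isNull(tl["ellipsoid"])) {
    NumericVector e = tl["ellipsoid"];
    T.has_ell = true;
    T.cx = e[0]; T.cy = e[1]; T.cz = e[2];
    T.ax = e[3]; T.ay = e[4]; T.az = e[5];
    T.props.push_back(Ops{e[6], e[7], e[8], e[9]});
    for (int i = 0; i < T.L; ++i)
      if (T.cz > T.zmin[i] && T.cz < T.zmax[i]) { T.ell_layer = i + 1; break; }
  }
  return T;
}

inline double ell_q(const Tissue& T, double x, double y, double z) {
  double qx = (x - T.cx) / T.ax, qy = (y - T.cy) / T.ay, qz = (z - T.cz) / T.az;
  return qx * qx + qy * qy + qz * qz;
}

int region_at(const Tissue& T, double x, double y, double z) {
  if (T.has_ell && ell_q(T, x, y, z) < 1.0) return T.ell_region();
  if (z < 0.0) return 0;
  for (int i = 0; i < T.L; ++i)
    if (z >= T.zmin[i] && z < T.zmax[i]) return i + 1;
  return T.L + 1;
}

// Smallest positive travel distance to the ellipsoid surface (+Inf if the
// ray misses). Stable quadratic root evaluation.
double ell_hit(const Tissue& T, const double* p, const double* d,
               bool from_inside) {
  double px = (p[0] - T.cx) / T.ax, py = (p[1] - T.cy) / T.ay,
         pz = (p[2] - T.cz) / T.az;
  double dx = d[0] / T.ax, dy = d[1] / T.ay, dz = d[2] / T.az;
  double A = dx * dx + dy * dy + dz * dz;
  double B = 2.0 * (px * dx + py * dy + pz * dz);
  double C = px * px + py * py + pz * pz - 1.0;
  if (A <= 0.0) return R_PosInf;
  double disc = B * B - 4.0 * A * C;
  if (disc < 0.0) return R_PosInf;
  double sd = std::sqrt(disc);
  double q = -0.5 * (B + (B >= 0.0 ? sd : -sd));
  double t1 = q / A;
  double t2 = (q != 0.0) ? C / q : R_PosInf;
  if (t1 > t2) std::swap(t1, t2);
  if (from_inside) return (t2 > 0.0) ? t2 : R_PosInf;
  if (t1 > 0.0) return t1;
  if (t2 > 0.0) return t2;
  return R_PosInf;
}

struct Hit { double d; int far; int surf; };  // surf: 0/1 layer plane, 2 ellipsoid

Hit boundary_hit(const Tissue& T, const double* p, const double* d, int reg) {
  Hit h{R_PosInf, -1, -1};
  if (T.has_ell && reg == T.ell_region()) {
    h.d = ell_hit(T, p, d, true);
    h.far = T.ell_layer;
    h.surf = 2;
    return h;
  }
  int i = reg - 1;  // layer array index
  if (d[2] < 0.0) {
    double t = (T.zmin[i] - p[2]) / d[2];
    if (t >= 0.0 && t < h.d) { h.d = t; h.far = reg - 1; h.surf = 0; }
  } else if (d[2] > 0.0 && std::isfinite(T.zmax[i])) {
    double t = (T.zmax[i] - p[2]) / d[2];
    if (t >= 0.0 && t < h.d) { h.d = t; h.far = reg + 1; h.surf = 1; }
  }
  if (T.has_ell && T.ell_layer == reg) {
    double t = ell_hit(T, p, d, false);
    if (t < h.d) { h.d = t; h.far = T.ell_region(); h.surf = 2; }
  }
  return h;
}

// Unpolarized Fresnel reflection probability with Snell refraction;
// returns 1 under total internal reflection.
double fresnel_R(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double st2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (st2 >= 1.0) return 1.0;
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

double hg_cost_one(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  return std::min(1.0, std::max(-1.0, c));
}

// Rotate a unit direction by polar angle acos(cost) and azimuth phi about
// itself (local-frame rotation, degenerate-pole branch near |uz|=1).
void rotate_dir(double* u, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 1.0 - 1e-12) {
    u[0] = sint * cosp;
    u[1] = sint * sinp;
    u[2] = cost * (uz >= 0.0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    u[0] = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    u[1] = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    u[2] = -sint * cosp * den + uz * cost;
  }
  double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

struct LaunchR {
  double x, y, z, ux, uy, uz, w, spec;
  int reg;
  bool dead;  // analog photon terminated as specular at launch
};

LaunchR do_launch(const List& src, const Tissue& T, MtStream& rng, int mode) {
  std::string type = as<std::string>(src["type"]);
  double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
  if (type == "DirectionalPoint") {
    NumericVector p = src["position"], d = src["direction"];
    x = p[0]; y = p[1]; z = p[2];
    ux = d[0]; uy = d[1]; uz = d[2];
  } else if (type == "IsotropicPoint") {
    NumericVector p = src["position"];
    x = p[0]; y = p[1]; z = p[2];
    double c = 2.0 * rng() - 1.0, ph = 2.0 * M_PI * rng();
    double s = std::sqrt(std::max(0.0, 1.0 - c * c));
    ux = s * std::cos(ph); uy = s * std::sin(ph); uz = c;
  } else if (type == "DirectionalCircular") {
    NumericVector p = src["position"];
    double r_out = as<double>(src["outer_radius"]);
    double r_in = as<double>(src["inner_radius"]);
    bool gauss = as<std::string>(src["profile"]) == "Gaussian";
    double conv = as<double>(src["convergence_angle"]);
    double r;
    if (gauss) {
      // beam_radius is the 1/e^2 intensity radius; radial coordinate of a
      // 2-D Gaussian is Rayleigh; rejection keeps r within the annulus
      double sig = as<double>(src["beam_radius"]) / 2.0;
      do {
        r = sig * std::sqrt(-2.0 * std::log(rng()));
      } while (r > r_out || r < r_in);
    } else {
      r = std::sqrt(r_in * r_in + rng() * (r_out * r_out - r_in * r_in));
    }
    double ph = 2.0 * M_PI * rng();
    x = p[0] + r * std::cos(ph);
    y = p[1] + r * std::sin(ph);
    z = p[2];
    // linear tilt toward the beam axis, 0 on axis -> convergence_angle at rim
    double th = (r_out > 0.0) ? conv * r / r_out : 0.0;
    ux = -std::sin(th) * std::cos(ph);
    uy = -std::sin(th) * std::sin(ph);
    uz = std::cos(th);
  } else if (type == "CustomPoint") {
    NumericVector p = src["position"], d = src["direction"],
                  pol = src["polar_range"], azi = src["azimuthal_range"];
    x = p[0]; y = p[1]; z = p[2];
    double c1 = std::cos(pol[0]), c2 = std::cos(pol[1]);
    double c = c1 + rng() * (c2 - c1);  // solid-angle uniform in the cap
    double ph = azi[0] + rng() * (azi[1] - azi[0]);
    double u3[3] = {d[0], d[1], d[2]};
    rotate_dir(u3, c, ph);
    ux = u3[0]; uy = u3[1]; uz = u3[2];
  } else {
    stop("unknown source type '%s'", type.c_str());
  }

  LaunchR L{};
  L.dead = false;
  if (z <= 0.0) {
    // external launch through the air/tissue interface at z = 0
    double n0 = T.props[0].n, n1 = T.props[1].n;
    double ci = uz;
    double Rf = fresnel_R(n0, n1, ci);
    if (mode == 0) {  // analog photons always carry weight exactly 1
      if (Rf >= 1.0 || (Rf > 0.0 && rng() < Rf)) {
        L.dead = true;
        L.spec = 1.0;
        L.w = 0.0;
        L.x = x; L.y = y; L.z = 0.0;
        L.ux = ux; L.uy = uy; L.uz = uz;
        L.reg = 0;
        return L;
      }
      L.w = 1.0;
      L.spec = 0.0;
    } else {
      L.w = 1.0 - Rf;
      L.spec = Rf;
      if (L.w <= 0.0) { L.dead = true; }
    }
    if (n0 != n1 && !L.dead) {
      double sc = n0 / n1;
      double st2 = sc * sc * (1.0 - ci * ci);
      ux *= sc; uy *= sc;
      uz = std::sqrt(std::max(0.0, 1.0 - st2));
    }
    z = NUDGE;
  } else {
    L.w = 1.0;
    L.spec = 0.0;
  }
  L.x = x; L.y = y; L.z = z;
  L.ux = ux; L.uy = uy; L.uz = uz;
  L.reg = L.dead ? 0 : region_at(T, x, y, z);
  return L;
}

}  // namespace

// [[Rcpp::export]]
double fresnel_cpp(double n1, double n2, double cos_incident) {
  return fresnel_R(n1, n2, cos_incident);
}

// [[Rcpp::export]]
NumericVector hg_cos_cpp(double g, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cost_one(g, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector rotate_direction_cpp(NumericVector direction, double cos_theta,
                                   double phi) {
  double u[3] = {direction[0], direction[1], direction[2]};
  rotate_dir(u, cos_theta, phi);
  return NumericVector::create(u[0], u[1], u[2]);
}

// [[Rcpp::export]]
IntegerVector region_index_cpp(NumericMatrix points, List tissue) {
  Tissue T = parse_tissue(tissue);
  int n = points.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = region_at(T, points(i, 0), points(i, 1), points(i, 2));
  return out;
}

// [[Rcpp::export]]
List distance_to_boundary_cpp(NumericVector position, NumericVector direction,
                              int region, List tissue) {
  Tissue T = parse_tissue(tissue);
  double p[3] = {position[0], position[1], position[2]};
  double d[3] = {direction[0], direction[1], direction[2]};
  Hit h = boundary_hit(T, p, d, region);
  return List::create(_["distance"] = h.d, _["far_region"] = h.far,
                      _["surface"] = h.surf);
}

// [[Rcpp::export]]
NumericMatrix sample_launch_cpp(List source, List tissue, int n, int seed,
                                int mode) {
  Tissue T = parse_tissue(tissue);
  MtStream rng(static_cast<uint32_t>(seed));
  NumericMatrix out(n, 10);
  colnames(out) = CharacterVector::create("x", "y", "z", "ux", "uy", "uz",
                                          "weight", "specular", "region",
                                          "dead");
  for (int i = 0; i < n; ++i) {
    LaunchR L = do_launch(source, T, rng, mode);
    out(i, 0) = L.x;  out(i, 1) = L.y;  out(i, 2) = L.z;
    out(i, 3) = L.ux; out(i, 4) = L.uy; out(i, 5) = L.uz;
    out(i, 6) = L.w;  out(i, 7) = L.spec;
    out(i, 8) = L.reg;
    out(i, 9) = L.dead ? 1.0 : 0.0;
  }
  return out;
}

// [[Rcpp::export]]
List run_engine_cpp(List cfg) {
  const int n_photons = as<int>(cfg["n_photons"]);
  const uint32_t seed = static_cast<uint32_t>(as<double>(cfg["seed"]));
  const int mode = as<int>(cfg["mode"]);    // 0 analog, 1 DAW, 2 CAW
  const int phase = as<int>(cfg["phase"]);  // 0 HG, 1 bidirectional
  const double rr_thresh = as<double>(cfg["rr_threshold"]);
  const double rr_p = as<double>(cfg["rr_survival"]);
  const int max_col = as<int>(cfg["max_collisions"]);
  const bool want_coll = as<bool>(cfg["collect_collision"]);
  const bool want_pp = as<bool>(cfg["collect_per_photon"]);
  Tissue T = parse_tissue(cfg["tissue"]);
  List src = cfg["source"];

  // optional (rho,z) absorption grid shared by AOfRhoAndZ / fluence tallies
  bool has_arz = cfg.containsElementNamed("arz") && !Rf_isNull(cfg["arz"]);
  double ar0 = 0, adr = 1, az0 = 0, adz = 1;
  int anr = 0, anz = 0;
  std::vector<double> arz_sum, arz_sum2, arz_scratch;
  std::vector<int> arz_stamp, arz_touched;
  if (has_arz) {
    List g = cfg["arz"];
    ar0 = as<double>(g["rho_start"]);
    anr = as<int>(g["rho_count"]);
    adr = (as<double>(g["rho_stop"]) - ar0) / anr;
    az0 = as<double>(g["z_start"]);
    anz = as<int>(g["z_count"]);
    adz = (as<double>(g["z_stop"]) - az0) / anz;
    arz_sum.assign(anr * anz, 0.0);
    arz_sum2.assign(anr * anz, 0.0);
    arz_scratch.assign(anr * anz, 0.0);
    arz_stamp.assign(anr * anz, -1);
  }

  MtStream rng(seed);
  const int nreg = T.n_regions();

  std::vector<double> ex_x, ex_y, ex_ux, ex_uy, ex_uz, ex_w, ex_t, ex_side;
  std::vector<double> coll_L, coll_J;  // row-appended, nreg columns
  std::vector<double> pp;              // per-photon: spec, deposited, exit_w, status

  long n_top = 0, n_bottom = 0, n_spec = 0, n_abs = 0, n_rr = 0, n_cap = 0;
  double spec_sum = 0.0, a_sum = 0.0, a_sum2 = 0.0;

  std::vector<double> Lr(nreg), Jr(nreg);

  for (int i = 0; i < n_photons; ++i) {
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    LaunchR la = do_launch(src, T, rng, mode);
    double a_photon = 0.0;
    int status = 0;  // 1 specular, 2 top, 3 bottom, 4 absorbed, 5 RR, 6 capped
    double exit_w = 0.0;

    if (la.dead) {
      ++n_spec;
      spec_sum += la.spec;
      status = 1;
    } else {
      spec_sum += la.spec;
      double x = la.x, y = la.y, z = la.z;
      double ux = la.ux, uy = la.uy, uz = la.uz;
      double w = la.w, t = 0.0;
      int reg = la.reg;
      std::fill(Lr.begin(), Lr.end(), 0.0);
      std::fill(Jr.begin(), Jr.end(), 0.0);
      int ncol = 0;

      auto deposit = [&](double amt, double px, double py, double pz) {
        a_photon += amt;
        if (has_arz) {
          double rho = std::sqrt(px * px + py * py);
          int ir = (int)std::floor((rho - ar0) / adr);
          if (ir < 0) ir = 0; else if (ir >= anr) ir = anr - 1;
          int iz = (int)std::floor((pz - az0) / adz);
          if (iz < 0) iz = 0; else if (iz >= anz) iz = anz - 1;
          int b = iz * anr + ir;
          if (arz_stamp[b] != i) {
            arz_stamp[b] = i;
            arz_touched.push_back(b);
            arz_scratch[b] = 0.0;
          }
          arz_scratch[b] += amt;
        }
      };

      while (status == 0) {
        const Ops& pr = T.props[reg];
        double mut = pr.mua + pr.mus;
        double coeff = (mode == 2) ? pr.mus : mut;
        double s = (coeff > 0.0) ? -std::log(rng()) / coeff : R_PosInf;
        double p3[3] = {x, y, z}, d3[3] = {ux, uy, uz};
        Hit h = boundary_hit(T, p3, d3, reg);

        if (!std::isfinite(s) && !std::isfinite(h.d)) {
          // nothing ahead and no interaction possible: absorb defensively
          if (pr.mua > 0.0) {
            deposit(w, x, y, z);
            w = 0.0;
            ++n_abs;
            status = 4;
          } else {
            ++n_cap;
            status = 6;
          }
          break;
        }

        if (h.d <= s) {
          // truncate the step at the boundary
          double len = h.d;
          if (mode == 2 && pr.mua > 0.0 && len > 0.0) {
            double f = std::exp(-pr.mua * len);
            deposit(w * (1.0 - f), x + ux * len * 0.5, y + uy * len * 0.5,
                    z + uz * len * 0.5);
            w *= f;
          }
          x += ux * len; y += uy * len; z += uz * len;
          t += len * pr.n / C_MM_NS;
          Lr[reg] += len;

          double nx = 0.0, ny = 0.0, nz = 1.0;
          if (h.surf == 2) {
            nx = (x - T.cx) / (T.ax * T.ax);
            ny = (y - T.cy) / (T.ay * T.ay);
            nz = (z - T.cz) / (T.az * T.az);
            double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
            nx /= nn; ny /= nn; nz /= nn;
          }
          double n1 = T.props[reg].n, n2 = T.props[h.far].n;
          double dot = ux * nx + uy * ny + uz * nz;
          double ci = std::fabs(dot);
          double Rf = fresnel_R(n1, n2, ci);
          if (Rf >= 1.0 || (Rf > 0.0 && rng() < Rf)) {
            ux -= 2.0 * dot * nx; uy -= 2.0 * dot * ny; uz -= 2.0 * dot * nz;
          } else {
            if (n1 != n2) {
              double sc = n1 / n2;
              double st2 = sc * sc * (1.0 - ci * ci);
              double ct = std::sqrt(std::max(0.0, 1.0 - st2));
              double sgn = (dot >= 0.0) ? 1.0 : -1.0;
              ux = sc * (ux - dot * nx) + sgn * ct * nx;
              uy = sc * (uy - dot * ny) + sgn * ct * ny;
              uz = sc * (uz - dot * nz) + sgn * ct * nz;
              double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
              ux /= nrm; uy /= nrm; uz /= nrm;
            }
            if (h.far == 0 || h.far == T.L + 1) {
              bool top = (h.far == 0);
              status = top ? 2 : 3;
              if (top) ++n_top; else ++n_bottom;
              exit_w = w;
              ex_x.push_back(x); ex_y.push_back(y);
              ex_ux.push_back(ux); ex_uy.push_back(uy); ex_uz.push_back(uz);
              ex_w.push_back(w); ex_t.push_back(t);
              ex_side.push_back(top ? 0.0 : 1.0);
              if (want_coll) {
                for (int r = 0; r < nreg; ++r) coll_L.push_back(Lr[r]);
                for (int r = 0; r < nreg; ++r) coll_J.push_back(Jr[r]);
              }
              break;
            }
            reg = h.far;
          }
          x += ux * NUDGE; y += uy * NUDGE; z += uz * NUDGE;
          continue;
        }

        // interior collision
        if (mode == 2 && pr.mua > 0.0) {
          double f = std::exp(-pr.mua * s);
          deposit(w * (1.0 - f), x + ux * s * 0.5, y + uy * s * 0.5,
                  z + uz * s * 0.5);
          w *= f;
        }
        x += ux * s; y += uy * s; z += uz * s;
        t += s * pr.n / C_MM_NS;
        Lr[reg] += s;
        Jr[reg] += 1.0;
        ++ncol;

        if (mode == 0) {
          if (mut > 0.0 && rng() < pr.mua / mut) {
            deposit(w, x, y, z);
            ++n_abs;
            status = 4;
            break;
          }
        } else if (mode == 1) {
          if (mut > 0.0) {
            double dep = w * pr.mua / mut;
            deposit(dep, x, y, z);
            w *= pr.mus / mut;
          }
        }

        if (phase == 1) {
          if (rng() < 0.5 * (1.0 - pr.g)) uz = -uz;
        } else {
          double cost = hg_cost_one(pr.g, rng());
          double phi = 2.0 * M_PI * rng();
          double u3[3] = {ux, uy, uz};
          rotate_dir(u3, cost, phi);
          ux = u3[0]; uy = u3[1]; uz = u3[2];
        }

        if (mode != 0 && w < 1e-300) {
          // weight has underflowed to numerical zero: the photon can no
          // longer contribute to any tally, so depositing the remainder
          // and terminating is exact
          deposit(w, x, y, z);
          w = 0.0;
          ++n_abs;
          status = 4;
          break;
        }
        if (mode != 0 && rr_thresh > 0.0 && w < rr_thresh) {
          if (rng() < rr_p) {
            w /= rr_p;
          } else {
            ++n_rr;
            status = 5;
            break;
          }
        }
        if (ncol >= max_col) {
          ++n_cap;
          status = 6;
          break;
        }
      }
    }

    a_sum += a_photon;
    a_sum2 += a_photon * a_photon;
    if (has_arz) {
      for (int b : arz_touched) {
        arz_sum[b] += arz_scratch[b];
        arz_sum2[b] += arz_scratch[b] * arz_scratch[b];
      }
      arz_touched.clear();
    }
    if (want_pp) {
      pp.push_back(la.spec);
      pp.push_back(a_photon);
      pp.push_back(exit_w);
      pp.push_back(static_cast<double>(status));
    }
  }

  int nex = static_cast<int>(ex_x.size());
  NumericMatrix exits(nex, 8);
  colnames(exits) = CharacterVector::create("x", "y", "ux", "uy", "uz",
                                            "weight", "time", "side");
  for (int i = 0; i < nex; ++i) {
    exits(i, 0) = ex_x[i];  exits(i, 1) = ex_y[i];
    exits(i, 2) = ex_ux[i]; exits(i, 3) = ex_uy[i]; exits(i, 4) = ex_uz[i];
    exits(i, 5) = ex_w[i];  exits(i, 6) = ex_t[i];  exits(i, 7) = ex_side[i];
  }

  List out = List::create(
      _["exits"] = exits,
      _["n_photons"] = n_photons,
      _["n_out_top"] = static_cast<double>(n_top),
      _["n_out_bottom"] = static_cast<double>(n_bottom),
      _["n_specular"] = static_cast<double>(n_spec),
      _["n_absorbed"] = static_cast<double>(n_abs),
      _["n_killed_rr"] = static_cast<double>(n_rr),
      _["n_capped"] = static_cast<double>(n_cap),
      _["specular_weight"] = spec_sum,
      _["a_total"] = a_sum,
      _["a_total_m2"] = a_sum2);

  if (want_coll) {
    NumericMatrix Lm(nreg, nex), Jm(nreg, nex);
    std::copy(coll_L.begin(), coll_L.end(), Lm.begin());
    std::copy(coll_J.begin(), coll_J.end(), Jm.begin());
    out["collision_L"] = transpose(Lm);
    out["collision_J"] = transpose(Jm);
  }
  if (has_arz) {
    NumericMatrix am(anr, anz), am2(anr, anz);
    std::copy(arz_sum.begin(), arz_sum.end(), am.begin());
    std::copy(arz_sum2.begin(), arz_sum2.end(), am2.begin());
    out["arz"] = am;
    out["arz_m2"] = am2;
  }
  if (want_pp) {
    int n = n_photons;
    NumericMatrix ppm(4, n);
    std::copy(pp.begin(), pp.end(), ppm.begin());
    NumericMatrix ppt = transpose(ppm);
    colnames(ppt) = CharacterVector::create("specular", "deposited",
                                            "exit_weight", "status");
    out["per_photon"] = ppt;
  }
  return out;
}
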