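// Constant-pH (semi-grand canonical) Metropolis Monte Carlo for the
// minimal-model flexible polyelectrolyte: explicit 3-D chain geometry with
// rigid bond lengths and valence angles, three-state rotatable bonds, and
// full screened Debye-Hueckel long-range interactions. Energies are kept in
// decimal-log units (weight 10^-F); acceptance uses exp(-ln10 * dF).
//
// Moves: (i) rotation of one rotatable bond to one of its two other states
// (rigidly rotating all downstream nodes about the bond axis), (ii) toggle
// of one site's protonation. Energy differences are computed incrementally:
// bond moves re-sum only the cross pairs (sites before x after the bond),
// site moves only the pairs involving that site. A debug mode recomputes
// the total energy periodically and tracks the worst drift.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double LN10 = 2.302585092994045684;
static const double INF = std::numeric_limits<double>::infinity();

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 scale(const Vec3& a, double f) {
  return {a.x * f, a.y * f, a.z * f};
}
static inline Vec3 add(const Vec3& a, const Vec3& b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
static inline Vec3 unit(const Vec3& a) { return scale(a, 1.0 / norm(a)); }

// Rodrigues rotation of p about the axis (origin o, unit direction u).
static inline Vec3 rotate_about(const Vec3& p, const Vec3& o, const Vec3& u,
                                double ca, double sa) {
  Vec3 v = sub(p, o);
  Vec3 term1 = scale(v, ca);
  Vec3 term2 = scale(cross(u, v), sa);
  Vec3 term3 = scale(u, dot(u, v) * (1.0 - ca));
  return add(o, add(term1, add(term2, term3)));
}

struct McModel {
  int n_sites, spacing, n_nodes, n_bonds, n_rot, rot_index;
  double bond_length, ang;           // ang = pi - valence angle
  double mu;                         // pH - pK
  double p_sigma, p_psi, p_omega;    // -log10 of sigma, psi, omega
  double eps_t, eps_g;               // -log10 of u_t, u_g (may be +Inf)
  double lB, kappa;
  bool lr_on;

  std::vector<Vec3> r;               // node coordinates
  std::vector<int> s;                // protonation (0/1) per site
  std::vector<int> c;                // bond states 0=t, 1=g+, 2=g-
  std::vector<int> rot_bond;         // 0-based bond index per rotatable bond

  double dihedral(int code) const {
    return code == 0 ? M_PI : (code == 1 ? M_PI / 3.0 : -M_PI / 3.0);
  }
  double eps_bond(int code) const { return code == 0 ? eps_t : eps_g; }
  int site_node(int i) const { return i * spacing; }

  double dh(double d) const {
    return (lB / d) * std::exp(-kappa * d) / LN10;
  }
  double dh_sites(int p, int q) const {
    Vec3 d = sub(r[site_node(p)], r[site_node(q)]);
    return dh(norm(d));
  }

  // rebuild all coordinates from the bond-state vector (canonical pose)
  void build_coords() {
    double l = bond_length;
    std::vector<double> phi(std::max(n_bonds, 1), M_PI);
    for (int a = 0; a < n_rot; ++a) phi[rot_bond[a]] = dihedral(c[a]);
    r.assign(n_nodes, {0.0, 0.0, 0.0});
    if (n_nodes >= 2) r[1] = {l, 0.0, 0.0};
    if (n_nodes >= 3)
      r[2] = {l + l * std::cos(ang), l * std::sin(ang), 0.0};
    for (int k = 1; k + 2 < n_nodes; ++k) {
      // dihedral of bond k (nodes k, k+1) places node k+2
      Vec3 bc = unit(sub(r[k + 1], r[k]));
      Vec3 n = unit(cross(sub(r[k], r[k - 1]), bc));
      Vec3 m = cross(n, bc);
      double ph = phi[k];
      Vec3 d = add(scale(bc, std::cos(ang)),
                   add(scale(m, std::sin(ang) * std::cos(ph)),
                       scale(n, -std::sin(ang) * std::sin(ph))));
      r[k + 2] = add(r[k + 1], scale(d, l));
    }
  }

  // local conformational energy terms touching rotatable bond a
  double rot_local(int a, int code) const {
    double e = (code != 0) ? p_sigma : 0.0;
    if (a > 0 && c[a - 1] != 0 && code != 0)
      e += (c[a - 1] == code) ? p_psi : p_omega;
    if (a + 1 < n_rot && c[a + 1] != 0 && code != 0)
      e += (c[a + 1] == code) ? p_psi : p_omega;
    return e;
  }

  double total_energy() const {
    double F = 0.0;
    for (int a = 0; a < n_rot; ++a) {
      if (c[a] != 0) F += p_sigma;
      if (a + 1 < n_rot && c[a] != 0 && c[a + 1] != 0)
        F += (c[a] == c[a + 1]) ? p_psi : p_omega;
    }
    for (int i = 0; i < n_sites; ++i) {
      if (!s[i]) continue;
      F += mu;
      if (i + 1 < n_sites && s[i + 1]) F += eps_bond(c[i]);
    }
    if (lr_on) {
      for (int p = 0; p + 2 < n_sites; ++p) {
        if (!s[p]) continue;
        for (int q = p + 2; q < n_sites; ++q)
          if (s[q]) F += dh_sites(p, q);
      }
    }
    return F;
  }
};

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(int n_sites, int spacing, double bond_length,
                double bond_angle, int rot_index,
                double pK, double sigma, double psi, double omega,
                double u_t, double u_g,
                double pH, double ionic_strength, double bjerrum_length,
                bool lr_enabled,
                double steps_eq, double steps_prod, double p_bond_move,
                int sampling_stride, double check_every,
                bool track_states,
                IntegerVector s_init, IntegerVector c_init) {
  McModel m;
  m.n_sites = n_sites;
  m.spacing = spacing;
  m.n_nodes = spacing * (n_sites - 1) + 1;
  m.n_bonds = m.n_nodes - 1;
  m.n_rot = (spacing >= 2 && n_sites > 1) ? n_sites - 1 : 0;
  m.rot_index = rot_index;
  m.bond_length = bond_length;
  m.ang = M_PI * (180.0 - bond_angle) / 180.0;
  m.mu = pH - pK;
  m.p_sigma = (sigma > 0) ? -std::log10(sigma) : INF;
  m.p_psi = (psi > 0) ? -std::log10(psi) : INF;
  m.p_omega = (omega > 0) ? -std::log10(omega) : INF;
  m.eps_t = (u_t > 0) ? -std::log10(u_t) : INF;
  m.eps_g = (u_g > 0) ? -std::log10(u_g) : INF;
  m.lB = bjerrum_length;
  m.kappa = std::sqrt(ionic_strength) / 0.304;
  m.lr_on = lr_enabled;

  m.rot_bond.resize(m.n_rot);
  for (int a = 0; a < m.n_rot; ++a)
    m.rot_bond[a] = a * spacing + rot_index - 1;

  m.s.assign(n_sites, 0);
  m.c.assign(std::max(m.n_rot, 0), 0);
  if (s_init.size() == n_sites)
    for (int i = 0; i < n_sites; ++i) m.s[i] = s_init[i];
  if (c_init.size() == m.n_rot)
    for (int a = 0; a < m.n_rot; ++a) m.c[a] = c_init[a] - 1;
  m.build_coords();

  double F = m.total_energy();
  double max_drift = 0.0;

  long long neq = (long long)steps_eq;
  long long nprod = (long long)steps_prod;
  long long chk = (long long)check_every;
  long long n_acc_bond = 0, n_try_bond = 0, n_acc_site = 0, n_try_site = 0;
  double sum_nu = 0.0, sum_g = 0.0;
  long long n_samp = 0;

  int n_state_codes = 0;
  std::vector<double> state_counts;
  if (track_states) {
    double codes = std::pow(2.0, n_sites) * std::pow(3.0, m.n_rot);
    if (codes <= 65536.0) {
      n_state_codes = (int)codes;
      state_counts.assign(n_state_codes, 0.0);
    }
  }

  std::vector<Vec3> scratch(m.n_nodes);
  RNGScope scope;

  for (long long step = 0; step < neq + nprod; ++step) {
    bool bond_move = (m.n_rot > 0) && (unif_rand() < p_bond_move);
    if (bond_move) {
      ++n_try_bond;
      int a = (int)(unif_rand() * m.n_rot);
      if (a >= m.n_rot) a = m.n_rot - 1;
      int old = m.c[a];
      int pick = (int)(unif_rand() * 2.0);
      int nw = (old + 1 + pick) % 3;
      double dF = m.rot_local(a, nw) - m.rot_local(a, old);
      // short-range electrostatics through this bond (segment a joins
      // sites a and a+1)
      if (m.s[a] && m.s[a + 1])
        dF += m.eps_bond(nw) - m.eps_bond(old);
      int jb = m.rot_bond[a];
      // the builder uses the IUPAC torsion sign, so advancing the dihedral
      // by dphi rotates the downstream part by -dphi about the bond axis
      double dphi = m.dihedral(nw) - m.dihedral(old);
      double ca = std::cos(dphi), sa = -std::sin(dphi);
      Vec3 axis = unit(sub(m.r[jb + 1], m.r[jb]));
      Vec3 origin = m.r[jb + 1];
      bool have_new = false;
      if (m.lr_on && std::isfinite(dF)) {
        // downstream sites are a+1..N-1; rotate their nodes into scratch
        for (int q = a + 1; q < n_sites; ++q) {
          int nd = m.site_node(q);
          scratch[nd] = rotate_about(m.r[nd], origin, axis, ca, sa);
        }
        have_new = true;
        for (int p = 0; p <= a; ++p) {
          if (!m.s[p]) continue;
          for (int q = std::max(a + 1, p + 2); q < n_sites; ++q) {
            if (!m.s[q]) continue;
            Vec3 dn = sub(scratch[m.site_node(q)], m.r[m.site_node(p)]);
            dF += m.dh(norm(dn)) - m.dh_sites(p, q);
          }
        }
      }
      bool accept = false;
      if (dF <= 0.0) accept = true;
      else if (std::isfinite(dF)) accept = unif_rand() < std::pow(10.0, -dF);
      if (accept) {
        ++n_acc_bond;
        m.c[a] = nw;
        for (int k = jb + 2; k < m.n_nodes; ++k)
          m.r[k] = rotate_about(m.r[k], origin, axis, ca, sa);
        (void)have_new;
        F += dF;
      }
    } else if (n_sites >= 1) {
      ++n_try_site;
      int i = (int)(unif_rand() * n_sites);
      if (i >= n_sites) i = n_sites - 1;
      int dn = m.s[i] ? -1 : +1;
      double dF = dn * m.mu;
      if (i > 0 && m.s[i - 1]) dF += dn * m.eps_bond(m.n_rot ? m.c[i - 1] : 0);
      if (i + 1 < n_sites && m.s[i + 1])
        dF += dn * m.eps_bond(m.n_rot ? m.c[i] : 0);
      if (m.lr_on) {
        for (int q = 0; q < n_sites; ++q) {
          if (q == i || !m.s[q]) continue;
          if (std::abs(q - i) < 2) continue;
          dF += dn * m.dh_sites(i, q);
        }
      }
      bool accept = false;
      if (dF <= 0.0) accept = true;
      else if (std::isfinite(dF)) accept = unif_rand() < std::pow(10.0, -dF);
      if (accept) {
        ++n_acc_site;
        m.s[i] += dn;
        F += dF;
      }
    }
    if (chk > 0 && (step + 1) % chk == 0) {
      double Ff = m.total_energy();
      if (std::isfinite(F) && std::isfinite(Ff))
        max_drift = std::max(max_drift, std::fabs(F - Ff));
      F = Ff;
    }
    if (step >= neq && ((step - neq) % sampling_stride == 0)) {
      int nu = 0;
      for (int i = 0; i < n_sites; ++i) nu += m.s[i];
      int g = 0;
      for (int a = 0; a < m.n_rot; ++a) g += (m.c[a] != 0);
      sum_nu += nu;
      sum_g += g;
      ++n_samp;
      if (n_state_codes > 0) {
        int code = 0;
        for (int i = n_sites - 1; i >= 0; --i) code = code * 2 + m.s[i];
        int cc = 0;
        for (int a = m.n_rot - 1; a >= 0; --a) cc = cc * 3 + m.c[a];
        code += cc * (1 << n_sites);
        state_counts[code] += 1.0;
      }
    }
  }

  double theta = n_samp ? sum_nu / (double)n_samp / n_sites : NA_REAL;
  double pg = (n_samp && m.n_rot) ? sum_g / (double)n_samp / m.n_rot
                                  : NA_REAL;
  IntegerVector s_out(n_sites), c_out(std::max(m.n_rot, 0));
  for (int i = 0; i < n_sites; ++i) s_out[i] = m.s[i];
  for (int a = 0; a < m.n_rot; ++a) c_out[a] = m.c[a] + 1;

  List out = List::create(
      _["theta"] = theta, _["p_gauche"] = pg,
      _["n_samples"] = (double)n_samp,
      _["acc_bond"] = n_try_bond ? (double)n_acc_bond / n_try_bond : NA_REAL,
      _["acc_site"] = n_try_site ? (double)n_acc_site / n_try_site : NA_REAL,
      _["max_drift"] = max_drift,
      _["final_energy"] = m.total_energy(),
      _["s"] = s_out, _["c"] = c_out);
  if (n_state_codes > 0) out["state_counts"] = NumericVector(
      state_counts.begin(), state_counts.end());
  return out;
}

// [[Rcpp::export(name = ".mc_energy_cpp")]]
double mc_energy_cpp(int n_sites, int spacing, double bond_length,
                     double bond_angle, int rot_index,
                     double pK, double sigma, double psi, double omega,
                     double u_t, double u_g,
                     double pH, double ionic_strength,
                     double bjerrum_length, bool lr_enabled,
                     IntegerVector s, IntegerVector c) {
  McModel m;
  m.n_sites = n_sites;
  m.spacing = spacing;
  m.n_nodes = spacing * (n_sites - 1) + 1;
  m.n_bonds = m.n_nodes - 1;
  m.n_rot = (spacing >= 2 && n_sites > 1) ? n_sites - 1 : 0;
  m.rot_index = rot_index;
  m.bond_length = bond_length;
  m.ang = M_PI * (180.0 - bond_angle) / 180.0;
  m.mu = pH - pK;
  m.p_sigma = (sigma > 0) ? -std::log10(sigma) : INF;
  m.p_psi = (psi > 0) ? -std::log10(psi) : INF;
  m.p_omega = (omega > 0) ? -std::log10(omega) : INF;
  m.eps_t = (u_t > 0) ? -std::log10(u_t) : INF;
  m.eps_g = (u_g > 0) ? -std::log10(u_g) : INF;
  m.lB = bjerrum_length;
  m.kappa = std::sqrt(ionic_strength) / 0.304;
  m.lr_on = lr_enabled;
  m.rot_bond.resize(m.n_rot);
  for (int a = 0; a < m.n_rot; ++a)
    m.rot_bond[a] = a * spacing + rot_index - 1;
  m.s.assign(n_sites, 0);
  m.c.assign(std::max(m.n_rot, 0), 0);
  for (int i = 0; i < n_sites && i < s.size(); ++i) m.s[i] = s[i];
  for (int a = 0; a < m.n_rot && a < c.size(); ++a) m.c[a] = c[a] - 1;
  m.build_coords();
  return m.total_energy();
}
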