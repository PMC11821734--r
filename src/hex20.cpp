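// Total-Lagrangian residual and tangent assembly for 20-node serendipity
// hexahedra with a Holmes-Mow (lambda = 0) solid matrix and a Donnan
// swelling pressure that is a constitutive function of J.
//
// First Piola-Kirchhoff stress:
//   P = mu e^Q (F - F^{-T}) + g(J) F^{-T},   g(J) = -pi(J) J,
//   Q = beta (I1 - 3 - 2 ln J),
//   pi(J) = RTphi (sqrt(cF^2 + cstar^2) - cstar),
//   cF = phi0 / (J - 1 + phi0) * c0F.
// The tangent is fully analytic; the material is hyperelastic (the swelling
// term derives from a potential in J), so the tangent is symmetric.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;
using arma::cube;

namespace {

// serendipity hex20 local node coordinates (corners, bottom/top edge
// midnodes, vertical edge midnodes) -- VTK quadratic-hex ordering
const double XI[20][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1},
  {0, -1, -1},  {1, 0, -1},  {0, 1, -1}, {-1, 0, -1},
  {0, -1, 1},   {1, 0, 1},   {0, 1, 1},  {-1, 0, 1},
  {-1, -1, 0},  {1, -1, 0},  {1, 1, 0},  {-1, 1, 0}};

// dN/dxi for all 20 shape functions at (xi, eta, zeta); out is 20 x 3
void hex20_dshape(double xi, double eta, double zeta, mat &out) {
  for (int a = 0; a < 20; ++a) {
    const double xa = XI[a][0], ya = XI[a][1], za = XI[a][2];
    if (xa != 0.0 && ya != 0.0 && za != 0.0) {          // corner
      const double s = xa * xi + ya * eta + za * zeta - 2.0;
      out(a, 0) = 0.125 * xa * (1 + ya * eta) * (1 + za * zeta) *
                  (s + (1 + xa * xi));
      out(a, 1) = 0.125 * ya * (1 + xa * xi) * (1 + za * zeta) *
                  (s + (1 + ya * eta));
      out(a, 2) = 0.125 * za * (1 + xa * xi) * (1 + ya * eta) *
                  (s + (1 + za * zeta));
    } else if (xa == 0.0) {                             // midside, xi dir
      out(a, 0) = -0.5 * xi * (1 + ya * eta) * (1 + za * zeta);
      out(a, 1) = 0.25 * ya * (1 - xi * xi) * (1 + za * zeta);
      out(a, 2) = 0.25 * za * (1 - xi * xi) * (1 + ya * eta);
    } else if (ya == 0.0) {
      out(a, 0) = 0.25 * xa * (1 - eta * eta) * (1 + za * zeta);
      out(a, 1) = -0.5 * eta * (1 + xa * xi) * (1 + za * zeta);
      out(a, 2) = 0.25 * za * (1 - eta * eta) * (1 + xa * xi);
    } else {                                            // za == 0
      out(a, 0) = 0.25 * xa * (1 - zeta * zeta) * (1 + ya * eta);
      out(a, 1) = 0.25 * ya * (1 - zeta * zeta) * (1 + xa * xi);
      out(a, 2) = -0.5 * zeta * (1 + xa * xi) * (1 + ya * eta);
    }
  }
}

void hex20_shape(double xi, double eta, double zeta, vec &N) {
  for (int a = 0; a < 20; ++a) {
    const double xa = XI[a][0], ya = XI[a][1], za = XI[a][2];
    if (xa != 0.0 && ya != 0.0 && za != 0.0) {
      N(a) = 0.125 * (1 + xa * xi) * (1 + ya * eta) * (1 + za * zeta) *
             (xa * xi + ya * eta + za * zeta - 2.0);
    } else if (xa == 0.0) {
      N(a) = 0.25 * (1 - xi * xi) * (1 + ya * eta) * (1 + za * zeta);
    } else if (ya == 0.0) {
      N(a) = 0.25 * (1 - eta * eta) * (1 + xa * xi) * (1 + za * zeta);
    } else {
      N(a) = 0.25 * (1 - zeta * zeta) * (1 + xa * xi) * (1 + ya * eta);
    }
  }
}

struct Quadrature {
  std::vector<double> x, w;   // tensor-product 3x3x3 Gauss
  std::vector<mat> dshape;    // 20 x 3 at each point
  std::vector<vec> shape;
  Quadrature() {
    const double g = std::sqrt(3.0 / 5.0);
    const double p[3] = {-g, 0.0, g};
    const double pw[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k) {
          x.push_back(p[i]); x.push_back(p[j]); x.push_back(p[k]);
          w.push_back(pw[i] * pw[j] * pw[k]);
          mat d(20, 3);
          hex20_dshape(p[i], p[j], p[k], d);
          dshape.push_back(d);
          vec N(20);
          hex20_shape(p[i], p[j], p[k], N);
          shape.push_back(N);
        }
  }
};

const Quadrature &quadrature() {
  static Quadrature q;
  return q;
}

}  // namespace

// Assemble internal force, tangent and field summaries.
// nodes: N x 3 reference coordinates; conn: E x 20 one-based connectivity;
// u: N x 3 displacements; mu, beta, c0F: per-element properties (c0F is the
// reference FCD magnitude, already ramp-scaled); RTphi = R*T*Phi;
// cstar = bath osmolarity; phi0 = reference fluid fraction.
// want_tangent / want_fields switch off unneeded work.
// [[Rcpp::export(name = ".hex20_system")]]
Rcpp::List hex20_system(const arma::mat &nodes, const arma::imat &conn,
                        const arma::mat &u, const arma::vec &mu,
                        const arma::vec &beta, const arma::vec &c0F,
                        double RTphi, double cstar, double phi0,
                        bool want_tangent, bool want_fields) {
  const int nnode = nodes.n_rows, nel = conn.n_rows, ndof = 3 * nnode;
  const Quadrature &q = quadrature();
  const int ngp = static_cast<int>(q.w.size());

  vec fint(ndof, arma::fill::zeros);
  arma::umat locs;
  vec vals;
  if (want_tangent) {
    locs.set_size(2, static_cast<arma::uword>(nel) * 3600);
    vals.set_size(static_cast<arma::uword>(nel) * 3600);
  }

  vec elem_J(nel, arma::fill::zeros), elem_cF(nel, arma::fill::zeros),
      elem_pi(nel, arma::fill::zeros);
  mat elem_sig;  // mean Cauchy stress, 6 comps (11,22,33,12,13,23)
  if (want_fields) elem_sig.zeros(nel, 6);

  bool bad = false;
  double minJ = arma::datum::inf;

  mat X(20, 3), ue(20, 3), dNdX(20, 3), Jm(3, 3);
  mat F(3, 3), Finv(3, 3), FinvT(3, 3), P(3, 3), A9(9, 9);
  mat Ke(60, 60);
  vec fe(60);
  const mat I3 = arma::eye(3, 3);

  for (int e = 0; e < nel && !bad; ++e) {
    for (int a = 0; a < 20; ++a) {
      const int n = conn(e, a) - 1;
      X.row(a) = nodes.row(n);
      ue.row(a) = u.row(n);
    }
    fe.zeros();
    if (want_tangent) Ke.zeros();

    for (int gp = 0; gp < ngp; ++gp) {
      const mat &dNdxi = q.dshape[gp];
      Jm = dNdxi.t() * X;                 // dX_j / dxi_i
      const double detJ0 = arma::det(Jm);
      if (detJ0 <= 0) { bad = true; break; }
      dNdX = dNdxi * arma::inv(Jm).t();
      F = I3 + ue.t() * dNdX;
      const double J = arma::det(F);
      if (J <= 1.0 - phi0 + 1e-12 || J <= 0.05) { bad = true; break; }
      if (J < minJ) minJ = J;

      const double mue = mu(e), be = beta(e);
      const double I1 = arma::accu(F % F);
      const double Q = be * (I1 - 3.0 - 2.0 * std::log(J));
      const double eQ = std::exp(Q);
      Finv = arma::inv(F);
      FinvT = Finv.t();

      const double denom = J - 1.0 + phi0;
      const double cF = phi0 / denom * c0F(e);
      const double root = std::sqrt(cF * cF + cstar * cstar);
      const double pi = RTphi * (root - cstar);
      const double dcFdJ = -cF / denom;
      const double dpidJ = (root > 0) ? RTphi * cF / root * dcFdJ : 0.0;
      const double g = -pi * J;
      const double gp_J = -(dpidJ * J + pi);  // g'(J)

      P = mue * eQ * (F - FinvT) + g * FinvT;

      const double wdet = q.w[gp] * detJ0;

      // internal force: f(3a+i) += dNdX(a,j) P(i,j)
      {
        mat PdN = dNdX * P.t();  // 20 x 3: (a,i) = sum_j dNdX(a,j) P(i,j)
        for (int a = 0; a < 20; ++a)
          for (int ii = 0; ii < 3; ++ii)
            fe(3 * a + ii) += wdet * PdN(a, ii);
      }

      if (want_tangent) {
        // A9(m, m') maps vec(dF) -> vec(dP), m = i + 3j (symmetric)
        A9.zeros();
        const double c1 = mue * eQ;          // identity term
        const double c2 = mue * eQ - g;      // FinvT dF^T FinvT term
        for (int ii = 0; ii < 3; ++ii)
          for (int jj = 0; jj < 3; ++jj) {
            const int m = ii + 3 * jj;
            A9(m, m) += c1;
            for (int ll = 0; ll < 3; ++ll)
              for (int kk = 0; kk < 3; ++kk)
                A9(m, ll + 3 * kk) += c2 * Finv(kk, ii) * Finv(jj, ll);
          }
        vec vFmT(9), vFiT(9);
        for (int ii = 0; ii < 3; ++ii)
          for (int jj = 0; jj < 3; ++jj) {
            vFmT(ii + 3 * jj) = F(ii, jj) - FinvT(ii, jj);
            vFiT(ii + 3 * jj) = FinvT(ii, jj);
          }
        A9 += (2.0 * be * mue * eQ) * (vFmT * vFmT.t());
        A9 += (gp_J * J) * (vFiT * vFiT.t());

        // K(3a+i, 3b+l) += dNdX(a,j) A9(i+3j, l+3k) dNdX(b,k);
        // block products over (i,l) with the symmetric mirror
        mat Ail(3, 3), tmp(20, 3), Kblk(20, 20);
        for (int ii = 0; ii < 3; ++ii)
          for (int ll = ii; ll < 3; ++ll) {
            for (int jj = 0; jj < 3; ++jj)
              for (int kk = 0; kk < 3; ++kk)
                Ail(jj, kk) = A9(ii + 3 * jj, ll + 3 * kk);
            tmp = dNdX * Ail;
            Kblk = tmp * dNdX.t();
            for (int a = 0; a < 20; ++a)
              for (int b = 0; b < 20; ++b) {
                Ke(3 * a + ii, 3 * b + ll) += wdet * Kblk(a, b);
                if (ll != ii)
                  Ke(3 * a + ll, 3 * b + ii) += wdet * Kblk(b, a);
              }
          }
      }

      if (want_fields) {
        const double wfrac = q.w[gp] / 8.0;  // sum of weights = 8
        elem_J(e) += wfrac * J;
        elem_cF(e) += wfrac * cF;
        elem_pi(e) += wfrac * pi;
        mat sig = (1.0 / J) * F * P.t();     // sigma = J^-1 P F^T (sym)
        sig = 0.5 * (sig + sig.t());
        elem_sig(e, 0) += wfrac * sig(0, 0);
        elem_sig(e, 1) += wfrac * sig(1, 1);
        elem_sig(e, 2) += wfrac * sig(2, 2);
        elem_sig(e, 3) += wfrac * sig(0, 1);
        elem_sig(e, 4) += wfrac * sig(0, 2);
        elem_sig(e, 5) += wfrac * sig(1, 2);
      }
    }
    if (bad) break;

    // scatter
    for (int a = 0; a < 20; ++a) {
      const int n = conn(e, a) - 1;
      for (int ii = 0; ii < 3; ++ii) fint(3 * n + ii) += fe(3 * a + ii);
    }
    if (want_tangent) {
      arma::uword base = static_cast<arma::uword>(e) * 3600;
      for (int a = 0; a < 20; ++a)
        for (int ii = 0; ii < 3; ++ii) {
          const arma::uword row = 3 * (conn(e, a) - 1) + ii;
          for (int b = 0; b < 20; ++b)
            for (int jj = 0; jj < 3; ++jj) {
              const arma::uword idx = base +
                static_cast<arma::uword>((3 * a + ii) * 60 + 3 * b + jj);
              locs(0, idx) = row;
              locs(1, idx) = 3 * (conn(e, b) - 1) + jj;
              vals(idx) = Ke(3 * a + ii, 3 * b + jj);
            }
        }
    }
  }

  Rcpp::List out;
  out["bad"] = bad;
  out["minJ"] = minJ;
  out["f"] = Rcpp::wrap(fint);
  if (want_tangent && !bad) {
    arma::sp_mat K(true, locs, vals, ndof, ndof);  // add duplicates
    out["K"] = Rcpp::wrap(K);
  }
  if (want_fields && !bad) {
    out["elem_J"] = Rcpp::wrap(elem_J);
    out["elem_cF"] = Rcpp::wrap(elem_cF);
    out["elem_pi"] = Rcpp::wrap(elem_pi);
    out["elem_sigma"] = Rcpp::wrap(elem_sig);
  }
  return out;
}

// Reference-configuration volume of each element (3x3x3 Gauss).
// [[Rcpp::export(name = ".hex20_volumes")]]
arma::vec hex20_volumes(const arma::mat &nodes, const arma::imat &conn) {
  const int nel = conn.n_rows;
  const Quadrature &q = quadrature();
  arma::vec vol(nel, arma::fill::zeros);
  mat X(20, 3), Jm(3, 3);
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 20; ++a) X.row(a) = nodes.row(conn(e, a) - 1);
    for (size_t gp = 0; gp < q.w.size(); ++gp) {
      Jm = q.dshape[gp].t() * X;
      vol(e) += q.w[gp] * arma::det(Jm);
    }
  }
  return vol;
}
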