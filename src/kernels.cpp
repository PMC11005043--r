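// Numerical kernels for per-frame featurization: sphere-point burial
// counting for Shrake-Rupley SASA and the Kabsch-Sander hydrogen-bond
// energy matrix. Everything else stays in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Total SASA of a site: per-atom scaled sphere points are tested for
// burial inside any neighbour's solvent sphere (squared distances).
// nbList holds 1-based neighbour indices into X.
// [[Rcpp::export]]
double cppSiteSasa(NumericMatrix X, List nbList, List ptsScaled,
                   NumericVector R2, NumericVector areaFactor) {
  int nsite = X.nrow();
  double tot = 0.0;
  std::vector<double> nx, ny, nz, nr2;
  for (int i = 0; i < nsite; ++i) {
    IntegerVector nb = nbList[i];
    NumericMatrix p = ptsScaled[i];
    int sp = p.nrow(), nn = nb.size();
    if (nn == 0) { tot += areaFactor[i] * sp; continue; }
    // contiguous neighbour buffers (column-major X scatters badly)
    nx.resize(nn); ny.resize(nn); nz.resize(nn); nr2.resize(nn);
    for (int j = 0; j < nn; ++j) {
      int a = nb[j] - 1;
      nx[j] = X(a, 0); ny[j] = X(a, 1); nz[j] = X(a, 2);
      nr2[j] = R2[a];
    }
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    const double *p1 = &p(0, 0), *p2 = &p(0, 1), *p3 = &p(0, 2);
    int acc = 0;
    for (int k = 0; k < sp; ++k) {
      double px = p1[k] + xi, py = p2[k] + yi, pz = p3[k] + zi;
      bool buried = false;
      for (int j = 0; j < nn; ++j) {
        double dx = px - nx[j], dy = py - ny[j], dz = pz - nz[j];
        if (dx * dx + dy * dy + dz * dz < nr2[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    tot += areaFactor[i] * acc;
  }
  return tot;
}

static inline double pdist(const NumericMatrix &A, int i,
                           const NumericMatrix &B, int j) {
  double dx = A(i, 0) - B(j, 0);
  double dy = A(i, 1) - B(j, 1);
  double dz = A(i, 2) - B(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Kabsch-Sander electrostatic hydrogen-bond energies, kcal/mol:
// E(i, j) for acceptor C=O of residue i and donor N-H of residue j,
// E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN); self and chain
// neighbours excluded, pairs with Calpha separation above 9 A skipped
// (standard DSSP screening), overlapping atoms (rON < 0.5 A) ignored.
// [[Rcpp::export]]
NumericMatrix cppHbondEnergy(NumericMatrix C, NumericMatrix O,
                             NumericMatrix N, NumericMatrix H,
                             NumericMatrix CA, LogicalVector hasH) {
  int n = C.nrow();
  NumericMatrix E(n, n);
  const double q = 27.888;
  for (int j = 0; j < n; ++j) {
    if (!hasH[j]) continue;
    for (int i = 0; i < n; ++i) {
      if (i == j || i == j - 1 || i == j + 1) continue;
      if (pdist(CA, i, CA, j) > 9.0) continue;
      double rON = pdist(O, i, N, j);
      if (rON < 0.5) continue;
      double rCH = pdist(C, i, H, j);
      double rOH = pdist(O, i, H, j);
      double rCN = pdist(C, i, N, j);
      E(i, j) = q * (1.0 / rON + 1.0 / rCH - 1.0 / rOH - 1.0 / rCN);
    }
  }
  return E;
}

// Pocket geometry in one pass: convex-hull volume of the site atoms
// (incremental hull), maximum pairwise distance ("length") and the mean
// distance of atoms to the hull surface ("depth").  Degenerate inputs
// (< 4 non-coplanar points) return volume 0 with degenerate = true.
// [[Rcpp::export]]
List cppPocketGeometry(NumericMatrix P) {
  int n = P.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = P(i,0); y[i] = P(i,1); z[i] = P(i,2); }
  double maxd2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > maxd2) maxd2 = d2;
    }
  double len = std::sqrt(maxd2);
  if (n < 4)
    return List::create(_["volume"] = 0.0, _["length"] = len,
                        _["depth"] = 0.0, _["degenerate"] = true);
  // seed tetrahedron
  int i1 = 0, i2 = 0, i3 = -1, i4 = -1;
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i]-x[i1], dy = y[i]-y[i1], dz = z[i]-z[i1];
    double d2 = dx*dx+dy*dy+dz*dz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  double e1x = x[i2]-x[i1], e1y = y[i2]-y[i1], e1z = z[i2]-z[i1];
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double vx = x[i]-x[i1], vy = y[i]-y[i1], vz = z[i]-z[i1];
    double cx = e1y*vz - e1z*vy, cy = e1z*vx - e1x*vz, cz = e1x*vy - e1y*vx;
    double c2 = cx*cx+cy*cy+cz*cz;
    if (c2 > best) { best = c2; i3 = i; }
  }
  double v3x = x[i3]-x[i1], v3y = y[i3]-y[i1], v3z = z[i3]-z[i1];
  double n0x = e1y*v3z - e1z*v3y, n0y = e1z*v3x - e1x*v3z,
         n0z = e1x*v3y - e1y*v3x;
  double n0n = std::sqrt(n0x*n0x+n0y*n0y+n0z*n0z);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double h = std::fabs(n0x*(x[i]-x[i1]) + n0y*(y[i]-y[i1]) +
                         n0z*(z[i]-z[i1]));
    if (h > best) { best = h; i4 = i; }
  }
  double e1n = std::sqrt(e1x*e1x+e1y*e1y+e1z*e1z);
  if (e1n < 1e-9 || n0n < 1e-9 || best < 1e-9 * std::max(1.0, e1n))
    return List::create(_["volume"] = 0.0, _["length"] = len,
                        _["depth"] = 0.0, _["degenerate"] = true);
  double ctx = (x[i1]+x[i2]+x[i3]+x[i4])/4.0;
  double cty = (y[i1]+y[i2]+y[i3]+y[i4])/4.0;
  double ctz = (z[i1]+z[i2]+z[i3]+z[i4])/4.0;
  std::vector<int> fa, fb, fc;
  std::vector<double> fnx, fny, fnz, foff;
  auto addFacet = [&](int a, int b, int c) {
    double ux = x[b]-x[a], uy = y[b]-y[a], uz = z[b]-z[a];
    double vx = x[c]-x[a], vy = y[c]-y[a], vz = z[c]-z[a];
    double nx2 = uy*vz - uz*vy, ny2 = uz*vx - ux*vz, nz2 = ux*vy - uy*vx;
    if (nx2*(ctx-x[a]) + ny2*(cty-y[a]) + nz2*(ctz-z[a]) > 0) {
      nx2 = -nx2; ny2 = -ny2; nz2 = -nz2;
    }
    fa.push_back(a); fb.push_back(b); fc.push_back(c);
    fnx.push_back(nx2); fny.push_back(ny2); fnz.push_back(nz2);
    foff.push_back(nx2*x[a] + ny2*y[a] + nz2*z[a]);
  };
  addFacet(i1, i2, i3); addFacet(i1, i2, i4);
  addFacet(i1, i3, i4); addFacet(i2, i3, i4);
  const double eps = 1e-9;
  for (int p = 0; p < n; ++p) {
    if (p == i1 || p == i2 || p == i3 || p == i4) continue;
    int nf = fa.size();
    std::vector<char> vis(nf, 0);
    bool any = false;
    for (int f = 0; f < nf; ++f) {
      double nn = std::sqrt(fnx[f]*fnx[f] + fny[f]*fny[f] + fnz[f]*fnz[f]);
      if (fnx[f]*x[p] + fny[f]*y[p] + fnz[f]*z[p] - foff[f] > eps * nn) {
        vis[f] = 1; any = true;
      }
    }
    if (!any) continue;
    // horizon edges = edges of visible facets seen exactly once
    std::vector<long long> keys;
    std::vector<std::pair<int,int> > edges;
    for (int f = 0; f < nf; ++f) {
      if (!vis[f]) continue;
      int vv[3] = { fa[f], fb[f], fc[f] };
      int pr[3][2] = { {vv[0],vv[1]}, {vv[1],vv[2]}, {vv[0],vv[2]} };
      for (int e = 0; e < 3; ++e) {
        int a = std::min(pr[e][0], pr[e][1]);
        int b = std::max(pr[e][0], pr[e][1]);
        keys.push_back((long long)a * (n + 1) + b);
        edges.push_back(std::make_pair(pr[e][0], pr[e][1]));
      }
    }
    // compact away visible facets
    int k = 0;
    for (int f = 0; f < nf; ++f) {
      if (vis[f]) continue;
      fa[k] = fa[f]; fb[k] = fb[f]; fc[k] = fc[f];
      fnx[k] = fnx[f]; fny[k] = fny[f]; fnz[k] = fnz[f]; foff[k] = foff[f];
      ++k;
    }
    fa.resize(k); fb.resize(k); fc.resize(k);
    fnx.resize(k); fny.resize(k); fnz.resize(k); foff.resize(k);
    for (size_t e = 0; e < edges.size(); ++e) {
      int cnt = 0;
      for (size_t e2 = 0; e2 < keys.size(); ++e2)
        if (keys[e2] == keys[e]) ++cnt;
      if (cnt == 1) addFacet(edges[e].first, edges[e].second, p);
    }
  }
  int nf = fa.size();
  // interior point = mean of hull vertices
  std::vector<char> used(n, 0);
  for (int f = 0; f < nf; ++f) { used[fa[f]] = used[fb[f]] = used[fc[f]] = 1; }
  double ix = 0, iy = 0, iz = 0; int nu = 0;
  for (int i = 0; i < n; ++i) if (used[i]) { ix += x[i]; iy += y[i];
    iz += z[i]; ++nu; }
  ix /= nu; iy /= nu; iz /= nu;
  double vol = 0.0;
  for (int f = 0; f < nf; ++f) {
    int a = fa[f], b = fb[f], c = fc[f];
    double ux = x[b]-x[a], uy = y[b]-y[a], uz = z[b]-z[a];
    double vx = x[c]-x[a], vy = y[c]-y[a], vz = z[c]-z[a];
    double cx = uy*vz - uz*vy, cy = uz*vx - ux*vz, cz = ux*vy - uy*vx;
    vol += std::fabs(cx*(x[a]-ix) + cy*(y[a]-iy) + cz*(z[a]-iz)) / 6.0;
  }
  double depth = 0.0;
  for (int i = 0; i < n; ++i) {
    double dmin = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double nn = std::sqrt(fnx[f]*fnx[f] + fny[f]*fny[f] + fnz[f]*fnz[f]);
      double d = (foff[f] - (fnx[f]*x[i] + fny[f]*y[i] + fnz[f]*z[i])) / nn;
      if (d < dmin) dmin = d;
    }
    depth += dmin;
  }
  depth /= n;
  if (depth < 0) depth = 0;
  return List::create(_["volume"] = vol, _["length"] = len,
                      _["depth"] = depth, _["degenerate"] = false);
}
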