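#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Table-free marching cubes specialised to binary fields at iso-level 0.5.
// Vertices sit on lattice edge midpoints. Each cell's surface polygons are
// traced over the cell faces; ambiguous faces (diagonal foreground pairs)
// are always resolved with the foreground connected, a rule that depends
// only on the shared face pattern, so adjacent cells agree and the mesh is
// watertight by construction. Out-of-range voxels are background, hence no
// explicit zero-padding is needed and masks touching the border still give
// closed surfaces.

static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// faces with corners ordered counter-clockwise as seen from outside the cell
static const int FACE[6][4] = {
  {0,4,7,3}, // -x
  {1,2,6,5}, // +x
  {0,1,5,4}, // -y
  {3,7,6,2}, // +y
  {0,3,2,1}, // -z
  {4,5,6,7}  // +z
};

// [[Rcpp::export]]
List cpp_marching_cubes(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nxy = (size_t)nx * ny;
  auto val = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return mask[(size_t)k * nxy + (size_t)j * nx + i] == TRUE ? 1 : 0;
  };

  std::unordered_map<long long, int> vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const long long NX = nx + 2, NY = ny + 2;

  // vertex on the cube edge between voxel-centre corners a and b
  auto vertex_for = [&](int ai, int aj, int ak, int bi, int bj, int bk) -> int {
    int axis = (ai != bi) ? 0 : ((aj != bj) ? 1 : 2);
    int i = std::min(ai, bi), j = std::min(aj, bj), k = std::min(ak, bk);
    long long key = (((long long)(k + 1) * NY + (j + 1)) * NX + (i + 1)) * 3 + axis;
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)vx.size();
    vid.emplace(key, id);
    vx.push_back(0.5 * (ai + bi));
    vy.push_back(0.5 * (aj + bj));
    vz.push_back(0.5 * (ak + bk));
    return id;
  };

  int v[8];
  int gi[8], gj[8], gk[8];
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        int s = 0;
        for (int c = 0; c < 8; ++c) {
          gi[c] = i + CORNER[c][0];
          gj[c] = j + CORNER[c][1];
          gk[c] = k + CORNER[c][2];
          v[c] = val(gi[c], gj[c], gk[c]);
          s += v[c];
        }
        if (s == 0 || s == 8) continue;

        // directed segments (startVertex -> endVertex), foreground kept on
        // the left when the face is viewed from outside the cell
        int seg_from[12], seg_to[12], nseg = 0;
        for (int f = 0; f < 6; ++f) {
          const int *F4 = FACE[f];
          for (int e = 0; e < 4; ++e) {
            int a = F4[e], b = F4[(e + 1) % 4];
            if (v[a] == 1 && v[b] == 0) {
              int p = -1, q = -1;
              for (int m = 1; m < 4; ++m) {
                int pa = F4[(e + m) % 4], pb = F4[(e + m + 1) % 4];
                if (v[pa] == 0 && v[pb] == 1) { p = pa; q = pb; break; }
              }
              int sv = vertex_for(gi[a], gj[a], gk[a], gi[b], gj[b], gk[b]);
              int ev = vertex_for(gi[p], gj[p], gk[p], gi[q], gj[q], gk[q]);
              seg_from[nseg] = sv; seg_to[nseg] = ev; ++nseg;
            }
          }
        }

        // trace closed loops; triangles are a triangle for 3-loops and a
        // centroid fan otherwise (canonical: independent of traversal
        // start, so the mesh is exactly symmetric under grid mirrors)
        bool used[12] = {false};
        for (int s0 = 0; s0 < nseg; ++s0) {
          if (used[s0]) continue;
          int loop[12], len = 0;
          int cur = s0;
          while (true) {
            used[cur] = true;
            loop[len++] = seg_from[cur];
            int nxt = -1;
            for (int t = 0; t < nseg; ++t)
              if (!used[t] && seg_from[t] == seg_to[cur]) { nxt = t; break; }
            if (nxt < 0) break;
            cur = nxt;
          }
          if (len == 3) {
            tri.push_back(loop[0]);
            tri.push_back(loop[2]);
            tri.push_back(loop[1]);
          } else if (len > 3) {
            double cxs = 0, cys = 0, czs = 0;
            for (int t = 0; t < len; ++t) {
              cxs += vx[loop[t]]; cys += vy[loop[t]]; czs += vz[loop[t]];
            }
            int cid = (int)vx.size();
            vx.push_back(cxs / len);
            vy.push_back(cys / len);
            vz.push_back(czs / len);
            for (int t = 0; t < len; ++t) {
              tri.push_back(cid);
              tri.push_back(loop[(t + 1) % len]);
              tri.push_back(loop[t]);
            }
          }
        }
      }

  const int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int a = 0; a < nv; ++a) {
    V(a, 0) = vx[a] * spacing[0];
    V(a, 1) = vy[a] * spacing[1];
    V(a, 2) = vz[a] * spacing[2];
  }
  const int nf = (int)tri.size() / 3;
  IntegerMatrix Fm(nf, 3);
  for (int a = 0; a < nf; ++a) {
    Fm(a, 0) = tri[3 * a] + 1;
    Fm(a, 1) = tri[3 * a + 1] + 1;
    Fm(a, 2) = tri[3 * a + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Census of directed half-edges: the mesh is closed and consistently
// oriented iff every directed edge occurs exactly once and its reverse
// occurs exactly once.
// [[Rcpp::export]]
List cpp_edge_census(IntegerMatrix faces, int nv) {
  std::unordered_map<long long, int> cnt;
  const int nf = faces.nrow();
  bool ok = true;
  for (int f = 0; f < nf; ++f) {
    int a[3] = {faces(f, 0), faces(f, 1), faces(f, 2)};
    for (int e = 0; e < 3; ++e) {
      int p = a[e], q = a[(e + 1) % 3];
      if (p == q) { ok = false; continue; }
      long long key = (long long)(p - 1) * nv + (q - 1);
      if (++cnt[key] > 1) ok = false;
    }
  }
  long long n_undirected = 0;
  if (ok) {
    for (auto &kv : cnt) {
      long long p = kv.first / nv, q = kv.first % nv;
      long long rev = q * nv + p;
      auto it = cnt.find(rev);
      if (it == cnt.end()) { ok = false; break; }
      if (p < q) ++n_undirected;
    }
  }
  return List::create(_["closed_oriented"] = ok,
                      _["n_edges"] = (double)n_undirected);
}

// Taubin lambda/mu smoothing: alternating shrink/inflate Laplacian steps
// that remove the staircase of binary marching-cubes surfaces with very
// little volume shrinkage. Connectivity is untouched.
// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F,
                                double lambda, double mu, int iterations) {
  const int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int>> nbr(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    nbr[a].push_back(b); nbr[a].push_back(c);
    nbr[b].push_back(a); nbr[b].push_back(c);
    nbr[c].push_back(a); nbr[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }
  NumericMatrix P = clone(V);
  NumericMatrix Q(nv, 3);
  const double factors[2] = {lambda, mu};
  for (int it = 0; it < iterations; ++it)
    for (int step = 0; step < 2; ++step) {
      double w = factors[step];
      for (int i = 0; i < nv; ++i) {
        if (nbr[i].empty()) {
          Q(i, 0) = P(i, 0); Q(i, 1) = P(i, 1); Q(i, 2) = P(i, 2);
          continue;
        }
        double mx = 0, my = 0, mz = 0;
        for (int j : nbr[i]) { mx += P(j, 0); my += P(j, 1); mz += P(j, 2); }
        double inv = 1.0 / nbr[i].size();
        Q(i, 0) = P(i, 0) + w * (mx * inv - P(i, 0));
        Q(i, 1) = P(i, 1) + w * (my * inv - P(i, 1));
        Q(i, 2) = P(i, 2) + w * (mz * inv - P(i, 2));
      }
      std::swap(P, Q);
    }
  return P;
}

// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = pts(i, c) - pts(j, c);
        s += diff * diff;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
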