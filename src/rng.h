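#pragma once
#include <cstdint>
#include <cmath>

// Small self-contained counter-seeded RNG so that per-voxel streamline draws
// are reproducible independently of iteration order and of R's global RNG.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Pcg32 {
  uint64_t state;
  uint64_t inc;

  // Seed from (global seed, voxel linear index, streamline index); any of the
  // components may be zero.
  void seed(uint64_t s, uint64_t voxel, uint64_t stream) {
    uint64_t x = s;
    uint64_t a = splitmix64(x);
    x ^= 0x632BE59BD9B4E019ULL * (voxel + 1);
    uint64_t b = splitmix64(x);
    x ^= 0x9E3779B97F4A7C15ULL * (stream + 1);
    uint64_t c = splitmix64(x);
    state = a ^ c;
    inc = (b << 1u) | 1u;
    next();
    state += c;
    next();
  }

  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }

  // uniform in (0,1)
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

// Draw t = mu.x from the bipolar Watson density f(t) propto exp(kappa t^2)
// on [-1,1] (uniform measure in t). Rejection from the exponential envelope
// g(t) propto exp(kappa t) on [0,1]; acceptance ratio exp(kappa (t^2 - t)) <= 1.
// kappa == 0 reduces to the uniform distribution on the sphere.
static inline double watson_t(double kappa, Pcg32 &rng) {
  if (kappa <= 0.0) return 2.0 * rng.unif() - 1.0;
  double ek = std::expm1(kappa);
  for (;;) {
    double u = rng.unif();
    double t = std::log1p(u * ek) / kappa;
    if (rng.unif() < std::exp(kappa * (t * t - t))) {
      return (rng.unif() < 0.5) ? -t : t;
    }
  }
}

// Full Watson draw about unit mean mu; e1,e2 complete the orthonormal frame.
static inline void watson_draw(const double mu[3], const double e1[3],
                               const double e2[3], double kappa, Pcg32 &rng,
                               double out[3]) {
  if (std::isinf(kappa)) {
    out[0] = mu[0]; out[1] = mu[1]; out[2] = mu[2];
    return;
  }
  double t = watson_t(kappa, rng);
  double r = std::sqrt(std::max(0.0, 1.0 - t * t));
  double phi = 2.0 * M_PI * rng.unif();
  double c = std::cos(phi), s = std::sin(phi);
  for (int d = 0; d < 3; ++d)
    out[d] = t * mu[d] + r * (c * e1[d] + s * e2[d]);
}
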